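small_cfg <- function(seed = 11, families = list(family_spec("f1", 500, 3)),
                      ...) {
  sim_config(seed = seed, n_chrom = 1, chrom_length = 20000,
             families = families, n_genes = 2, ...)
}

test_that("identical config yields byte-identical FASTA and GFF", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- generate_genome(small_cfg())
    write_fasta(sim$genome, file.path(d, "g.fa"))
    write_gff3(sim$features, file.path(d, "f.gff3"))
  }
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "f.gff3")),
                   readLines(file.path(d2, "f.gff3")))
})

test_that("no families means no repeat annotations", {
  sim <- generate_genome(small_cfg(families = list()))
  expect_false(any(sim$features$type == "transposable_element"))
  expect_equal(nrow(sim$truth$rip_sites), 0)
})

test_that("background GC tracks the configured fraction", {
  cfg <- sim_config(seed = 2, n_chrom = 1, chrom_length = 100000,
                    gc_background = 0.5, families = list(), n_genes = 0)
  sim <- generate_genome(cfg)
  gc <- Biostrings::letterFrequency(sim$genome[[1]], "GC",
                                    as.prob = TRUE)[1]
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(gc_background = 1.4), "gc_background")
  expect_error(sim_config(rip_rate = -0.1), "rip_rate")
  expect_error(sim_config(meth_context_weights = c(CpG = 0, CHG = 0,
                                                   CHH = 0)),
               "meth_context_weights")
  expect_error(family_spec("x", unit_length = 200), "unit_length")
  expect_error(family_spec("x", target_identity = 0.5), "target_identity")
  expect_error(sim_config(chrom_length = 300,
                          families = list(family_spec("x", 500))),
               "chrom_length")
})

test_that("apply_rip with rate 0 changes nothing", {
  copies <- c(a = "ACGTACGT", b = "ACGTACGT")
  out <- apply_rip(copies, 0)
  expect_identical(out$copies, copies)
  expect_equal(nrow(out$sites), 0)
})

test_that("apply_rip site count is binomial at the configured rate", {
  seq <- strrep("CGAT", 100)                     # 100 CpG sites per copy
  out <- apply_rip(c(only = seq), 0.2,
                   c(CpA = 0, CpC = 0, CpG = 1, CpT = 0), seed = 99)
  n <- nrow(out$sites)
  sigma <- sqrt(100 * 0.2 * 0.8)
  expect_gte(n, 20 - 3 * sigma)
  expect_lte(n, 20 + 3 * sigma)
  expect_true(all(out$sites$context == "CpG"))
})

test_that("context weights confine mutations to the chosen context", {
  out <- make_rip_family(5, rate = 0.5,
                         weights = c(CpA = 1, CpC = 0, CpG = 0, CpT = 0))
  expect_gt(nrow(out$sites), 0)
  expect_true(all(out$sites$context == "CpA"))
})

test_that("planted sites exactly equal the pre/post sequence diff", {
  out <- make_rip_family(7, n_copies = 4, rate = 0.15)
  anc <- strsplit(out$ancestor, "")[[1]]
  diffs <- list()
  for (cid in names(out$copies)) {
    b <- strsplit(out$copies[[cid]], "")[[1]]
    at <- which(b != anc)
    expect_true(all(anc[at] == "C" & b[at] == "T"))
    diffs[[cid]] <- tibble::tibble(copy_id = cid, pos = at)
  }
  diffs <- dplyr::bind_rows(diffs)
  expect_equal(
    dplyr::arrange(diffs, copy_id, pos),
    dplyr::arrange(out$sites[, c("copy_id", "pos")], copy_id, pos),
    ignore_attr = TRUE
  )
})

test_that("planted milRNA precursors fold below -20 kcal/mol", {
  cfg <- small_cfg(seed = 21, families = list(),
                   smrna_loci = list(locus_spec("milRNA"),
                                     locus_spec("milRNA", strand = "-")))
  sim <- generate_genome(cfg)
  loci <- sim$truth$loci
  expect_equal(nrow(loci), 2)
  for (i in seq_len(nrow(loci))) {
    hp <- as.character(Biostrings::subseq(sim$genome[[loci$chrom[i]]],
                                          loci$hairpin_start[i],
                                          loci$hairpin_end[i]))
    expect_lte(fold_rna(hp)$mfe, -20)
  }
})

test_that("simulated smRNA alignments are deterministic and in range", {
  cfg <- small_cfg(seed = 31, families = list(),
                   smrna_loci = list(locus_spec("milRNA"),
                                     locus_spec("disiRNA")))
  sim <- generate_genome(cfg)
  a1 <- simulate_smrna(sim$genome, sim$truth$loci, 2, seed = 4)
  a2 <- simulate_smrna(sim$genome, sim$truth$loci, 2, seed = 4)
  expect_identical(a1, a2)
  lens <- a1$end - a1$start + 1L
  expect_true(all(lens >= 18 & lens <= 30))
  none <- simulate_smrna(sim$genome, sim$truth$loci[0, ], 0, seed = 4)
  expect_equal(nrow(none), 0)
  bad <- sim$truth$loci
  bad$end[1] <- 10^7
  expect_error(simulate_smrna(sim$genome, bad, 0, seed = 4), "outside")
})

test_that("methylome simulation honours rates and symmetric CpG planting", {
  cfg <- small_cfg(seed = 41,
                   families = list(family_spec("f1", 800, 4)),
                   meth_rate_te = 0.2, meth_rate_genic = 0)
  sim <- generate_genome(cfg)
  meth <- simulate_methylome(sim)
  te <- sim$features[sim$features$type == "transposable_element", ]
  tr <- meth$truth
  in_te <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(te))) {
    in_te <- in_te | (tr$chrom == te$chrom[i] & tr$pos >= te$start[i] &
                        tr$pos <= te$end[i])
  }
  expect_true(all(in_te))                       # genic rate 0
  cpg <- tr[tr$context == "CpG" & tr$strand == "+", ]
  partner <- paste(cpg$chrom, cpg$pos + 1, "-") %in%
    paste(tr$chrom, tr$pos, tr$strand)
  expect_true(all(partner))                     # symmetric planting
})
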