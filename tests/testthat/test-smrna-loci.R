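## alignments builder: n reads of length len tiled across a span
mk_aln <- function(n, span_start, span_len, strand = "+", chrom = "chr1",
                   len = 20L) {
  starts <- as.integer(round(seq(span_start,
                                 span_start + span_len - len,
                                 length.out = n)))
  tibble::tibble(chrom = chrom, start = starts, end = starts + len - 1L,
                 name = paste0("r", seq_len(n), "_", strand),
                 score = 1, strand = strand) |>
    dplyr::arrange(chrom, start)
}

test_that("locus density arithmetic matches the quoted thresholds", {
  aln <- mk_aln(30, 1, 100)                 # 30 reads over 100 bp
  loci <- scan_loci(aln, min_density = 270)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$length, 100L)
  expect_equal(loci$density, 300)
  sparse <- mk_aln(5, 1, 100)               # 50 reads/kb
  expect_equal(nrow(scan_loci(sparse, min_density = 60, min_reads = 0)), 0)
  expect_equal(nrow(scan_loci(aln[0, ])), 0)
})

test_that("reads merge across gaps up to max_gap on either strand", {
  a <- dplyr::arrange(dplyr::bind_rows(
    mk_aln(10, 1, 50, "+"),
    mk_aln(10, 90, 50, "-")), chrom, start)   # 40 bp gap between blocks
  one <- scan_loci(a, min_density = 0, max_gap = 50, min_reads = 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$plus_reads, 10)
  expect_equal(one$minus_reads, 10)
  two <- scan_loci(a, min_density = 0, max_gap = 30, min_reads = 0)
  expect_equal(nrow(two), 2)
})

test_that("unsorted alignments are rejected with advice to sort", {
  aln <- mk_aln(5, 1, 100)[c(3, 1, 2, 4, 5), ]
  expect_error(scan_loci(aln), "sorted")
})

test_that("multi-mapped reads are down-weighted fractionally", {
  aln <- mk_aln(10, 1, 60)
  aln$name <- rep(c("dup", "uniq1", "uniq2", "uniq3", "uniq4"), each = 2)
  aln$name[3:10] <- paste0("u", 3:10)       # 'dup' maps twice
  frac <- scan_loci(aln, min_density = 0, min_reads = 0)
  expect_equal(frac$n_reads, 9)             # 8 unique + 2 * 1/2
  all_w <- scan_loci(aln, min_density = 0, min_reads = 0, multimap = "all")
  expect_equal(all_w$n_reads, 10)
  uniq <- scan_loci(aln, min_density = 0, min_reads = 0,
                    multimap = "unique")
  expect_equal(uniq$n_reads, 8)
})

test_that("MFEI follows amfe / GC%", {
  expect_equal(mfei(-40, 100, 50), 0.8)
  expect_equal(mfei(0, 100, 50), 0)
  expect_equal(mfei(-30, 120, 40), 0.625)
  expect_true(is.na(mfei(-30, 120, 0)))
})

test_that("bundled folding recognises hairpins and refuses junk", {
  hp <- paste0(strrep("GC", 15), "TTTT", strrep("GC", 15))
  f <- fold_rna(hp)
  expect_lte(f$mfe, -20)
  db <- strsplit(f$structure, "")[[1]]
  expect_equal(sum(db == "("), sum(db == ")"))
  p <- f$partner
  paired <- which(p > 0)
  expect_true(all(p[p[paired]] == paired))  # pairing is an involution
  flat <- fold_rna(strrep("A", 60))
  expect_equal(flat$mfe, 0)
  expect_equal(flat$structure, strrep(".", 60))
})

test_that("milRNA criteria reject in the documented order", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 600)))
  base <- tibble::tibble(
    chrom = "chr1", start = 201L, end = 300L, length = 100L,
    plus_reads = 300, minus_reads = 40, n_reads = 340,
    density = 3400, strand_ratio = 7.5, dominant_strand = "+",
    class = "none"
  )
  aln <- mk_aln(5, 201, 100)
  r1 <- call_milrna(base, aln, genome)
  expect_equal(r1$fail_reason, "strand_ratio")     # 7.5 < 10
  low <- dplyr::mutate(base, minus_reads = 10, n_reads = 310,
                       strand_ratio = 30, density = 250)
  r2 <- call_milrna(low, aln, genome)
  expect_equal(r2$fail_reason, "density")          # 250 <= 270
  nofold <- dplyr::mutate(base, minus_reads = 0, n_reads = 300,
                          strand_ratio = Inf)
  r3 <- call_milrna(nofold, aln, genome)
  expect_equal(r3$fail_reason, "mfe_mfei")         # poly-A cannot fold
  expect_equal(r3$class, "none")
})

test_that("disiRNA calls need balance and density, and defer to milRNA", {
  loci <- tibble::tibble(
    chrom = "chr1", start = c(1L, 601L, 1201L),
    end = c(500L, 1100L, 1700L), length = 500L,
    plus_reads = c(30, 30, 3), minus_reads = c(28, 2, 3),
    n_reads = c(58, 32, 6), density = c(116, 64, 12),
    strand_ratio = c(30 / 28, 15, 1), dominant_strand = "+",
    class = c("none", "none", "none")
  )
  out <- call_disirna(loci)
  expect_equal(out$class, c("disiRNA", "none", "none"))
  milred <- dplyr::mutate(loci, class = c("milRNA", "none", "none"))
  expect_equal(call_disirna(milred)$class[1], "milRNA")
})

test_that("raising thresholds never increases accepted loci", {
  cfg <- sim_config(seed = 55, n_chrom = 1, chrom_length = 30000,
                    families = list(),
                    smrna_loci = list(locus_spec("milRNA"),
                                      locus_spec("milRNA", strand = "-"),
                                      locus_spec("disiRNA"),
                                      locus_spec("disiRNA")))
  sim <- generate_genome(cfg)
  aln <- simulate_smrna(sim$genome, sim$truth$loci, 2, seed = 55)
  n_at <- function(...) {
    l <- classify_loci(aln, sim$genome, ...)
    sum(l$class != "none")
  }
  base <- n_at()
  expect_lte(n_at(min_density_mil = 500, min_density_disi = 120), base)
  expect_lte(n_at(strand_fold = 50), base)
  expect_lte(n_at(mfei_min = 1.5), base)
  expect_lte(n_at(balance_max = 1.01), base)
})

test_that("planted loci are recovered and background stays clean", {
  cfg <- sim_config(seed = 77, n_chrom = 2, chrom_length = 30000,
                    families = list(),
                    smrna_loci = list(
                      locus_spec("milRNA", chrom = "chr1", start = 10000),
                      locus_spec("disiRNA", chrom = "chr2", start = 5000)))
  sim <- generate_genome(cfg)
  aln <- simulate_smrna(sim$genome, sim$truth$loci, 2, seed = 77)
  loci <- classify_loci(aln, sim$genome)
  truth <- sim$truth$loci
  for (i in seq_len(nrow(truth))) {
    hit <- loci$chrom == truth$chrom[i] & loci$start <= truth$end[i] &
      loci$end >= truth$start[i]
    expect_equal(loci$class[hit], truth$class[i])
  }
  expect_equal(sum(loci$class != "none"), nrow(truth))
})
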