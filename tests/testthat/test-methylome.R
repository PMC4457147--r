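toy_genome <- Biostrings::DNAStringSet(c(chr1 = "TTCGACAGTCATTAAC"))
##                                             1234567890123456
## plus-strand Cs: 3 (CpG), 6 (CHG: C-A-G), 10 (CHH: C-A-T),
## 16 (3' truncated)

test_that("context classification follows the CpG/CHG/CHH rules", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(3L, 6L, 10L),
                          strand = "+")
  out <- classify_context(toy_genome, sites)
  expect_equal(out$context, c("CpG", "CHG", "CHH"))
  expect_false(any(out$context_truncated))
})

test_that("minus-strand context reads 3' towards lower coordinates", {
  ## minus C at plus-pos 4 (G): next on minus is complement(pos 3 = C) = G
  out <- classify_context(toy_genome,
                          tibble::tibble(chrom = "chr1", pos = 4L,
                                         strand = "-"))
  expect_equal(out$context, "CpG")
  ## minus C at 8: next = complement(A at 7) = T, then complement(C at 6)
  ## = G, so CHG
  out2 <- classify_context(toy_genome,
                           tibble::tibble(chrom = "chr1", pos = 8L,
                                          strand = "-"))
  expect_equal(out2$context, "CHG")
})

test_that("truncated 3' context is CHH and flagged", {
  out <- classify_context(toy_genome,
                          tibble::tibble(chrom = "chr1", pos = 16L,
                                         strand = "+"))
  expect_equal(out$context, "CHH")
  expect_true(out$context_truncated)
  expect_error(
    classify_context(toy_genome,
                     tibble::tibble(chrom = "chr1", pos = 1L,
                                    strand = "+")),
    "not a cytosine")
})

test_that("binary calls apply inclusive coverage and fraction thresholds", {
  expect_true(binary_call(5, 0))
  expect_false(binary_call(1, 9))
  expect_true(binary_call(2, 2, min_cov = 4, min_frac = 0.5))  # boundary
  expect_false(binary_call(1, 2, min_cov = 4))
  expect_equal(binary_call(c(5, 1, 2), c(0, 9, 2)),
               c(TRUE, FALSE, TRUE))
})

test_that("context composition is over methylated calls only", {
  calls <- tibble::tibble(
    context = c("CpG", "CpG", "CHG", "CHH"),
    is_methylated = c(TRUE, TRUE, TRUE, FALSE)
  )
  cc <- context_composition(calls)
  expect_equal(sum(cc$fraction), 1)
  expect_equal(cc$fraction[cc$context == "CpG"], 2 / 3)
  empty <- context_composition(dplyr::mutate(calls,
                                             is_methylated = FALSE))
  expect_equal(nrow(empty), 0)
})

test_that("genome methylation rate is the methylated fraction", {
  calls <- tibble::tibble(is_methylated = c(rep(TRUE, 18),
                                            rep(FALSE, 982)))
  expect_equal(genome_methylation_rate(calls), 0.018)
  expect_equal(genome_methylation_rate(
    tibble::tibble(is_methylated = rep(TRUE, 5))), 1)
  expect_equal(genome_methylation_rate(
    tibble::tibble(is_methylated = rep(FALSE, 5))), 0)
})

test_that("feature methylation level is sites per kilobase", {
  feats <- tibble::tibble(chrom = "chr1", start = 1001L, end = 3000L,
                          type = "transposable_element", ID = "te1")
  calls <- tibble::tibble(chrom = "chr1",
                          pos = c(1100L, 1500L, 2000L, 2500L, 2999L, 5000L),
                          is_methylated = c(rep(TRUE, 5), TRUE))
  fm <- feature_methylation(feats, calls)
  expect_equal(fm$mc_sites, 5L)
  expect_equal(fm$level, 2.5)
  expect_equal(fm$feature_type, "TE")
  none <- feature_methylation(feats,
                              dplyr::mutate(calls, is_methylated = FALSE))
  expect_equal(none$level, 0)
  bad <- dplyr::mutate(feats, end = 900L)
  expect_error(feature_methylation(bad, calls), "length")
})

test_that("gene methylation equals the sum over its exons and introns", {
  cfg <- sim_config(seed = 19, n_chrom = 1, chrom_length = 30000,
                    families = list(family_spec("f1", 500, 3)),
                    n_genes = 3)
  sim <- generate_genome(cfg)
  calls <- add_binary_calls(simulate_methylome(sim)$calls)
  fm <- feature_methylation(
    sim$features[sim$features$type %in% c("gene", "exon", "intron"), ],
    calls)
  genes <- fm[fm$feature_type == "gene", ]
  parts <- fm[fm$feature_type != "gene", ]
  part_of <- sim$features$Parent[match(parts$feature_id,
                                       sim$features$ID)]
  for (g in genes$feature_id) {
    expect_equal(sum(parts$mc_sites[part_of == g]),
                 genes$mc_sites[genes$feature_id == g])
  }
})

test_that("stored contexts re-derive from the genome", {
  cfg <- sim_config(seed = 23, n_chrom = 1, chrom_length = 20000,
                    families = list(family_spec("f1", 500, 3)))
  sim <- generate_genome(cfg)
  calls <- simulate_methylome(sim)$calls
  sub <- calls[sample.int(nrow(calls), 500), ]
  re <- classify_context(sim$genome, sub[, c("chrom", "pos", "strand")])
  expect_equal(re$context, sub$context)
})

test_that("CpG dinucleotide fraction counts either-strand methylation", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("CGTT", 100)))  # 100 CpGs
  calls <- tibble::tibble(
    chrom = "chr1",
    pos = c(4L * (0:32) + 1L, 4L * (0:10) + 2L),   # 33 plus Cs, 11 minus Gs
    strand = rep(c("+", "-"), c(33, 11)),
    is_methylated = TRUE
  )
  ## minus calls sit on the same first 11 dinucleotides as plus calls
  expect_equal(cpg_site_methylation_fraction(g, calls), 0.33)
  expect_true(is.na(cpg_site_methylation_fraction(
    Biostrings::DNAStringSet(c(chr1 = "ATATATAT")), calls)))
  all_m <- tibble::tibble(chrom = "chr1", pos = 4L * (0:99) + 1L,
                          strand = "+", is_methylated = TRUE)
  expect_equal(cpg_site_methylation_fraction(g, all_m), 1)
})
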