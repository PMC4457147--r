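te_feats <- tibble::tibble(
  chrom = "chr1", type = "transposable_element",
  start = c(1001L, 3001L), end = c(2000L, 4000L), strand = "+",
  ID = c("te1", "te2"), te_class = "I", superfamily = "LTR"
)

mk_reads <- function(starts, mismatches = 0L, hits = 1L) {
  tibble::tibble(chrom = "chr1", start = starts, end = starts + 74L,
                 name = paste0("r", seq_along(starts)), score = 1,
                 strand = "+", mismatches = mismatches, hits = hits)
}

test_that("expression flags apply the mismatch and multi-hit filters", {
  expect_false(any(flag_te_expression(te_feats, mk_reads(integer(0)))$expressed))
  ## a read with 3 mismatches does not count
  r3 <- flag_te_expression(te_feats, mk_reads(1100L, mismatches = 3L))
  expect_false(r3$expressed[r3$te_id == "te1"])
  ## nor does a multi-mapper
  rm <- flag_te_expression(te_feats, mk_reads(1100L, hits = 3L))
  expect_false(rm$expressed[rm$te_id == "te1"])
  ok <- flag_te_expression(te_feats, mk_reads(c(1100L, 1500L)))
  expect_true(ok$expressed[ok$te_id == "te1"])
  expect_false(ok$expressed[ok$te_id == "te2"])
  expect_error(flag_te_expression(te_feats, mk_reads(1100L)[, 1:6]),
               "extension")
})

test_that("adding reads never silences an expressed TE", {
  base <- mk_reads(c(1100L, 1500L))
  more <- dplyr::arrange(dplyr::bind_rows(base, mk_reads(1700L)), start)
  e1 <- flag_te_expression(te_feats, base)
  e2 <- flag_te_expression(te_feats, more)
  expect_true(all(e2$expressed[e1$expressed]))
})

test_that("planted expressed-TE set is recovered exactly", {
  cfg <- sim_config(seed = 61, n_chrom = 2, chrom_length = 40000,
                    families = list(family_spec("f1", 600, 5,
                                                expressed_frac = 0.5),
                                    family_spec("f2", 500, 4,
                                                superfamily = "TIR",
                                                expressed_frac = 0.4)))
  sim <- generate_genome(cfg)
  rnaseq <- simulate_rnaseq(sim$genome, sim$truth$te_copies, seed = 61)
  te <- sim$features[sim$features$type == "transposable_element", ]
  expr <- flag_te_expression(te, rnaseq)
  expect_setequal(expr$te_id[expr$expressed], sim$truth$expressed_te)
})

test_that("crosstab rows partition the records exactly", {
  for (seed in c(101, 202)) {
    rec <- random_te_records(seed)
    ct <- tibble::as_tibble(crosstab(rec))
    tot <- ct[ct$te_set == "Total", ]
    for (pair in list(c("RIP", "Non-RIP"), c("5mC", "Non-5mC"))) {
      sub <- ct[ct$te_set %in% pair, ]
      for (e in c("Yes", "No")) {
        a <- sub[sub$expressed == e, ]
        b <- tot[tot$expressed == e, ]
        expect_equal(colSums(a[, -(1:2)]), colSums(b[, -(1:2)]) * 1)
      }
    }
    expect_equal(sum(tot$num), nrow(rec))
  }
})

test_that("crosstab cells equal brute-force tabulation", {
  rec <- random_te_records(303, n = 40)
  ct <- tibble::as_tibble(crosstab(rec))
  for (set in c("Total", "RIP", "RIP & 5mC", "Non-RIP & non-5mC")) {
    for (e in c(TRUE, FALSE)) {
      row <- ct[ct$te_set == set &
                  ct$expressed == ifelse(e, "Yes", "No"), ]
      for (sf in c("LTR", "TIR", "LINE")) {
        expect_equal(row[[sf]], oracle_crosstab_cell(rec, set, e, sf))
      }
    }
  }
})

test_that("superfamily/class consistency is enforced", {
  rec <- random_te_records(5, n = 10)
  feats <- tibble::tibble(chrom = "chr1", start = 1:10 * 100L,
                          end = 1:10 * 100L + 50L, ID = rec$te_id,
                          te_class = "II", superfamily = "LTR")
  expect_error(
    te_activity_records(feats, tibble::tibble(te_id = character(),
                                              expressed = logical()),
                        NULL, NULL),
    "inconsistent")
})

test_that("silencing fraction covers the documented cases", {
  mk <- function(n, silenced) {
    tibble::tibble(te_id = as.character(seq_len(n)), te_class = "I",
                   superfamily = "LTR",
                   expressed = rep(c(FALSE, TRUE),
                                   c(silenced, n - silenced)),
                   rip_affected = TRUE, methylated = TRUE)
  }
  expect_equal(silencing_fraction(mk(10, 10)), 1.0)
  expect_equal(silencing_fraction(mk(100, 93)), 0.93)
  none <- dplyr::mutate(mk(5, 5), rip_affected = FALSE)
  expect_true(is.na(silencing_fraction(none)))
  ## class II records never count
  mixed <- dplyr::bind_rows(mk(10, 9),
                            dplyr::mutate(mk(10, 0), te_class = "II",
                                          superfamily = "TIR"))
  expect_equal(silencing_fraction(mixed), 0.9)
})

test_that("defense regions: none on a clean genome, monotone thresholds", {
  cfg <- sim_config(seed = 71, n_chrom = 1, chrom_length = 50000,
                    families = list(), n_genes = 0)
  sim <- generate_genome(cfg)
  tracks <- windowed_tracks(sim$genome)
  expect_equal(nrow(detect_defense_regions(tracks)), 0)
  cfg2 <- sim_config(seed = 72, n_chrom = 1, chrom_length = 50000,
                     rip_rate = 0.2,
                     rip_context_weights = c(CpA = 1, CpC = 0, CpG = 0.2,
                                             CpT = 0),
                     families = list(
                       family_spec("cl", 900, 5, 1.0, strand_mix = 0,
                                   unit_gc = 0.4, chrom = "chr1",
                                   start = 20000)))
  sim2 <- generate_genome(cfg2)
  calls <- add_binary_calls(simulate_methylome(sim2)$calls)
  fams <- extract_repeat_families(sim2$genome, sim2$features)
  sites <- dplyr::bind_rows(lapply(fams, call_rip_sites))
  tracks2 <- windowed_tracks(sim2$genome, sites, calls)
  loose <- detect_defense_regions(tracks2, gc_max = 0.5, cri_min = -1,
                                  rip_min = 1, mc_min = 1)
  strict <- detect_defense_regions(tracks2, gc_max = 0.45, cri_min = 0.2,
                                   rip_min = 10, mc_min = 20)
  expect_lte(nrow(strict), nrow(loose))
})

test_that("tidiers summarise crosstabs consistently", {
  rec <- random_te_records(9)
  ct <- crosstab(rec)
  long <- tidy(ct)
  expect_true(all(c("te_set", "superfamily", "pct") %in% names(long)))
  g <- glance(ct)
  expect_equal(g$n_records, nrow(rec))
  expect_equal(g$n_expressed + g$n_silent, nrow(rec))
})
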