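# Independent brute-force oracles and small fixture builders used across
# the suite.  The oracles deliberately use naive character loops so they
# share no code path with the implementation they check.

# dinucleotide counting by explicit iteration
oracle_rip_indices <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  cnt <- c(TA = 0, AT = 0, CA = 0, TG = 0, AC = 0, GT = 0)
  for (i in seq_len(length(b) - 1)) {
    d <- paste0(b[i], b[i + 1])
    if (d %in% names(cnt)) cnt[d] <- cnt[d] + 1
  }
  product <- if (cnt[["AT"]] > 0) cnt[["TA"]] / cnt[["AT"]] else NA_real_
  substrate <- if (cnt[["AC"]] + cnt[["GT"]] > 0) {
    (cnt[["CA"]] + cnt[["TG"]]) / (cnt[["AC"]] + cnt[["GT"]])
  } else NA_real_
  list(product = product, substrate = substrate,
       cri = if (is.na(product) || is.na(substrate)) NA_real_
             else product - substrate)
}

# cross-tabulation by explicit double loop
oracle_crosstab_cell <- function(records, set, expressed, superfamily) {
  n <- 0
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    in_set <- switch(set,
      "Total" = TRUE,
      "RIP" = r$rip_affected,
      "Non-RIP" = !r$rip_affected,
      "5mC" = r$methylated,
      "Non-5mC" = !r$methylated,
      "RIP & 5mC" = r$rip_affected && r$methylated,
      "Non-RIP & non-5mC" = !r$rip_affected && !r$methylated)
    if (in_set && r$expressed == expressed &&
        r$superfamily == superfamily) {
      n <- n + 1
    }
  }
  n / nrow(records) * 100
}

# identical repeat copies carrying RIP as the only mutational process
make_rip_family <- function(seed, n_copies = 4, len = 600, rate = 0.1,
                            weights = c(CpA = 0.25, CpC = 0.10,
                                        CpG = 0.55, CpT = 0.10)) {
  withr::with_seed(seed, {
    unit <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                         prob = c(0.225, 0.275, 0.275, 0.225)),
                  collapse = "")
    copies <- setNames(rep(unit, n_copies),
                       paste0("c", seq_len(n_copies)))
    out <- apply_rip(copies, rate, weights)
    out$ancestor <- unit
    out
  })
}

random_te_records <- function(seed, n = 60) {
  withr::with_seed(seed, {
    sf <- sample(c("LINE", "LTR", "DIRS", "PLE", "TIR", "helitron",
                   "MITE"), n, replace = TRUE)
    tibble::tibble(
      te_id = paste0("te", seq_len(n)),
      te_class = unname(c(LINE = "I", LTR = "I", DIRS = "I", PLE = "I",
                          TIR = "II", helitron = "II", MITE = "II")[sf]),
      superfamily = sf,
      expressed = sample(c(TRUE, FALSE), n, replace = TRUE),
      rip_affected = sample(c(TRUE, FALSE), n, replace = TRUE),
      methylated = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
  })
}
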