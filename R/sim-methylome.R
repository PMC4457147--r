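## Forward model of the bisulfite methylome.

## Enumerate every cytosine in the genome (both strands) with its sequence
## context.  `pos` is the plus-strand coordinate of the C on its own strand
## (for minus-strand cytosines, the position of the plus-strand G).
cytosine_table <- function(genome) {
  out <- lapply(names(genome), function(cn) {
    v <- chrom_chars(genome, cn)
    L <- length(v)
    p_plus <- which(v == "C")
    n1 <- ifelse(p_plus + 1L <= L, v[pmin(p_plus + 1L, L)], NA)
    n2 <- ifelse(p_plus + 2L <= L, v[pmin(p_plus + 2L, L)], NA)
    ctx_plus <- ifelse(!is.na(n1) & n1 == "G", "CpG",
                ifelse(!is.na(n2) & n2 == "G", "CHG", "CHH"))
    trunc_plus <- is.na(n1) | (!(!is.na(n1) & n1 == "G") & is.na(n2))
    tri_plus <- paste0("C", ifelse(is.na(n1), "N", n1),
                       ifelse(is.na(n2), "N", n2))
    p_minus <- which(v == "G")
    m1 <- ifelse(p_minus - 1L >= 1L, v[pmax(p_minus - 1L, 1L)], NA)
    m2 <- ifelse(p_minus - 2L >= 1L, v[pmax(p_minus - 2L, 1L)], NA)
    ctx_minus <- ifelse(!is.na(m1) & m1 == "C", "CpG",
                 ifelse(!is.na(m2) & m2 == "C", "CHG", "CHH"))
    trunc_minus <- is.na(m1) | (!(!is.na(m1) & m1 == "C") & is.na(m2))
    tri_minus <- paste0("C",
                        ifelse(is.na(m1), "N", complement_chr(m1)),
                        ifelse(is.na(m2), "N", complement_chr(m2)))
    tibble(
      chrom = cn,
      pos = c(p_plus, p_minus),
      strand = rep(c("+", "-"), c(length(p_plus), length(p_minus))),
      context = c(ctx_plus, ctx_minus),
      context_truncated = c(trunc_plus, trunc_minus),
      trinucleotide = c(tri_plus, tri_minus)
    )
  })
  bind_rows(out) |> arrange(.data$chrom, .data$pos, .data$strand)
}

## logical: which rows of a position tibble fall inside any interval
positions_in_intervals <- function(positions, intervals) {
  if (nrow(intervals) == 0 || nrow(positions) == 0) {
    return(rep(FALSE, nrow(positions)))
  }
  q <- GenomicRanges::GRanges(positions$chrom,
                              IRanges::IRanges(positions$pos, positions$pos))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start,
                                               intervals$end))
  IRanges::overlapsAny(q, s)
}

#' Simulate a bisulfite methylome over a (synthetic) genome
#'
#' Cytosines inside methylation-targeted TE intervals are methylated at
#' `meth_rate_te`, all other cytosines at `meth_rate_genic`; the context mix
#' among methylated sites follows `meth_context_weights`.  CpG methylation
#' is planted symmetrically (both strands of a CpG dinucleotide together),
#' as maintenance methyltransferases do, so the fraction of CpG
#' *dinucleotides* carrying methylation matches the per-cytosine targets.
#' Read counts are then drawn per cytosine: Poisson coverage, binomial
#' methylated-read counts at `bs_meth_level` (methylated sites) or
#' `bs_error` (failed conversion at unmethylated sites).
#'
#' Context is recomputed from the genome for every call, never assumed.
#'
#' @param genome a [Biostrings::DNAStringSet], or a `defense_sim` object
#'   (in which case `features` and `cfg` are taken from it).
#' @param features planted annotation tibble (needs `type`,
#'   `chrom`, `start`, `end`; TE rows are `type ==
#'   "transposable_element"`).
#' @param cfg the [sim_config()] used to generate the genome.
#' @param te_meth_ids optional TE `ID`s targeted for methylation; defaults
#'   to every TE (or to the simulator's `methylated_family` truth when a
#'   `defense_sim` is given).
#' @return list with `calls` (CX-style tibble: `chrom`, `pos`, `strand`,
#'   `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`)
#'   and `truth` (tibble of planted methylated cytosines).
#' @export
simulate_methylome <- function(genome, features = NULL, cfg = NULL,
                               te_meth_ids = NULL) {
  if (inherits(genome, "defense_sim")) {
    sim <- genome
    genome <- sim$genome
    features <- features %||% sim$features
    cfg <- cfg %||% sim$config
    if (is.null(te_meth_ids)) {
      tc <- sim$truth$te_copies
      te_meth_ids <- tc$te_id[tc$methylated_family]
    }
  }
  if (is.null(features) || is.null(cfg)) {
    abort("simulate_methylome: features and cfg are required")
  }
  withr::with_seed(cfg$seed + 1L, {
    cyt <- cytosine_table(genome)
    te <- features[features$type == "transposable_element", , drop = FALSE]
    if (!is.null(te_meth_ids)) te <- te[te$ID %in% te_meth_ids, , drop = FALSE]
    in_te <- positions_in_intervals(cyt, te)
    meth <- rep(FALSE, nrow(cyt))
    wn <- cfg$meth_context_weights / sum(cfg$meth_context_weights)
    key <- paste(cyt$chrom, cyt$pos, cyt$strand)
    for (cls in c("te", "genic")) {
      rows <- which(in_te == (cls == "te"))
      rate <- if (cls == "te") cfg$meth_rate_te else cfg$meth_rate_genic
      target <- round(rate * length(rows))
      if (target == 0) next
      t_cpg <- round(target * wn[["CpG"]])
      t_chg <- round(target * wn[["CHG"]])
      t_chh <- max(target - t_cpg - t_chg, 0)
      ## symmetric CpG: pick dinucleotides, methylate both strands
      anchors <- rows[cyt$strand[rows] == "+" & cyt$context[rows] == "CpG"]
      n_dinuc <- min(round(t_cpg / 2), length(anchors))
      if (n_dinuc > 0) {
        a <- if (length(anchors) == 1) anchors else sample(anchors, n_dinuc)
        meth[a] <- TRUE
        partner <- match(paste(cyt$chrom[a], cyt$pos[a] + 1L, "-"), key)
        meth[partner[!is.na(partner)]] <- TRUE
      }
      for (ctx in c("CHG", "CHH")) {
        t_ctx <- if (ctx == "CHG") t_chg else t_chh
        pool <- rows[cyt$context[rows] == ctx & !meth[rows]]
        n_ctx <- min(t_ctx, length(pool))
        if (n_ctx > 0) {
          meth[if (length(pool) == 1) pool else sample(pool, n_ctx)] <- TRUE
        }
      }
    }
    cov <- rpois(nrow(cyt), cfg$bs_coverage)
    p_read <- ifelse(meth, cfg$bs_meth_level, cfg$bs_error)
    cm <- rbinom(nrow(cyt), cov, p_read)
    calls <- tibble(
      chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
      count_methylated = cm, count_unmethylated = cov - cm,
      context = cyt$context, trinucleotide = cyt$trinucleotide
    )
    truth <- cyt[meth, c("chrom", "pos", "strand", "context")]
    list(calls = calls, truth = truth)
  })
}
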