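## Methylome scoring: context classification, binary calls, summaries.

#' Classify the sequence context of cytosines
#'
#' CpG if the next base (on the cytosine's strand) is G; else CHG if the
#' base after next is G; else CHH (H = A, C or T).  Cytosines within 2 bp
#' of the strand's 3' chromosome end, whose context cannot be fully read,
#' are classified CHH and flagged as truncated.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param sites tibble with `chrom`, `pos` (1-based plus-strand coordinate
#'   of the C), `strand`.
#' @return `sites` with `context` and `context_truncated` columns added.
#' @export
classify_context <- function(genome, sites) {
  stopifnot_fields(sites, c("chrom", "pos", "strand"), "sites")
  if (nrow(sites) == 0) {
    sites$context <- character(0)
    sites$context_truncated <- logical(0)
    return(sites)
  }
  context <- character(nrow(sites))
  truncated <- logical(nrow(sites))
  for (cn in unique(sites$chrom)) {
    v <- chrom_chars(genome, cn)
    L <- length(v)
    idx <- which(sites$chrom == cn)
    p <- sites$pos[idx]
    s <- sites$strand[idx]
    base <- ifelse(s == "+", v[p], complement_chr(v[p]))
    if (any(base != "C")) {
      abort(paste0("classify_context: base at ", cn, ":",
                   p[which(base != "C")[1]],
                   " is not a cytosine on the given strand"))
    }
    n1 <- ifelse(s == "+",
                 ifelse(p + 1 <= L, v[pmin(p + 1, L)], NA),
                 ifelse(p - 1 >= 1, complement_chr(v[pmax(p - 1, 1)]), NA))
    n2 <- ifelse(s == "+",
                 ifelse(p + 2 <= L, v[pmin(p + 2, L)], NA),
                 ifelse(p - 2 >= 1, complement_chr(v[pmax(p - 2, 1)]), NA))
    ctx <- ifelse(!is.na(n1) & n1 == "G", "CpG",
           ifelse(!is.na(n2) & n2 == "G", "CHG", "CHH"))
    context[idx] <- ctx
    truncated[idx] <- is.na(n1) | (ctx != "CpG" & is.na(n2))
  }
  sites$context <- context
  sites$context_truncated <- truncated
  sites
}

#' Binary methylation call for a cytosine
#'
#' A cytosine is called methylated iff its coverage reaches `min_cov` and
#' its methylated-read fraction reaches `min_frac` (both comparisons
#' inclusive).  The thresholds are explicit configuration, not inferred
#' from data.
#'
#' @param count_methylated,count_unmethylated nonnegative read counts
#'   (vectorised).
#' @param min_cov minimum total coverage (default 4).
#' @param min_frac minimum methylated fraction (default 0.5).
#' @return logical vector.
#' @export
#' @examples
#' binary_call(c(5, 1, 2), c(0, 9, 2))
binary_call <- function(count_methylated, count_unmethylated,
                        min_cov = 4, min_frac = 0.5) {
  stopifnot(all(count_methylated >= 0), all(count_unmethylated >= 0))
  cov <- count_methylated + count_unmethylated
  cov >= min_cov & ifelse(cov > 0, count_methylated / cov, 0) >= min_frac
}

#' Add binary methylation calls to a cytosine-report tibble
#'
#' @param calls tibble with `count_methylated` and `count_unmethylated`.
#' @inheritParams binary_call
#' @return `calls` with an `is_methylated` logical column.
#' @export
add_binary_calls <- function(calls, min_cov = 4, min_frac = 0.5) {
  stopifnot_fields(calls, c("count_methylated", "count_unmethylated"),
                   "calls")
  calls$is_methylated <- binary_call(calls$count_methylated,
                                     calls$count_unmethylated,
                                     min_cov, min_frac)
  calls
}

#' Context composition of methylated cytosines
#'
#' @param calls tibble with `context` and `is_methylated`.
#' @return tibble `context`, `n`, `fraction` over methylated calls
#'   (fractions sum to 1); zero rows when nothing is methylated.
#' @export
context_composition <- function(calls) {
  stopifnot_fields(calls, c("context", "is_methylated"), "calls")
  m <- calls[calls$is_methylated, , drop = FALSE]
  if (nrow(m) == 0) {
    return(tibble(context = character(), n = integer(),
                  fraction = numeric()))
  }
  m |>
    count(.data$context, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}

#' Genome-wide cytosine methylation rate
#'
#' @param calls tibble covering all assayed cytosines, with
#'   `is_methylated`.
#' @return fraction of assayed cytosines called methylated.
#' @export
genome_methylation_rate <- function(calls) {
  stopifnot_fields(calls, "is_methylated", "calls")
  if (nrow(calls) == 0) return(NA_real_)
  mean(calls$is_methylated)
}

#' Per-feature methylation level (methylated sites per kb)
#'
#' Counts methylated cytosines (strand-agnostic: both strands of a
#' symmetric CpG are two sites) inside each feature interval and reports
#' the level as sites per kilobase.
#'
#' @param features tibble with `chrom`, `start`, `end`, `type` and an `ID`
#'   column; `type == "transposable_element"` is reported as `"TE"`.
#' @param calls tibble with `chrom`, `pos`, `is_methylated`.
#' @return tibble: `feature_id`, `feature_type`, `chrom`, `start`, `end`,
#'   `length`, `mc_sites`, `level` (sites/kb).
#' @export
feature_methylation <- function(features, calls) {
  stopifnot_fields(features, c("chrom", "start", "end", "type", "ID"),
                   "features")
  stopifnot_fields(calls, c("chrom", "pos", "is_methylated"), "calls")
  if (nrow(features) == 0) abort("feature_methylation: no features given")
  if (any(features$end < features$start)) {
    abort("feature_methylation: zero- or negative-length feature")
  }
  m <- calls[calls$is_methylated, , drop = FALSE]
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start,
                                                 features$end))
  n <- if (nrow(m) == 0) {
    rep(0L, nrow(features))
  } else {
    mgr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$pos, m$pos))
    GenomicRanges::countOverlaps(fgr, mgr)
  }
  len <- features$end - features$start + 1L
  tibble(
    feature_id = features$ID,
    feature_type = ifelse(features$type == "transposable_element", "TE",
                          features$type),
    chrom = features$chrom, start = features$start, end = features$end,
    length = len, mc_sites = as.integer(n), level = n / (len / 1000)
  )
}

#' Aggregate feature methylation by feature type
#'
#' @param fm output of [feature_methylation()].
#' @return tibble: `feature_type`, `n_features`, `total_mc_sites`,
#'   `mean_level` (mean of per-feature sites/kb).
#' @export
feature_methylation_summary <- function(fm) {
  fm |>
    group_by(.data$feature_type) |>
    summarise(n_features = n(), total_mc_sites = sum(.data$mc_sites),
              mean_level = mean(.data$level), .groups = "drop")
}

#' Fraction of CpG dinucleotides carrying methylation
#'
#' The numerator counts CpG dinucleotides with a methylated call on either
#' strand; the denominator counts all CpG dinucleotides in the regions.
#' One symmetric CpG is therefore one unit here, while it contributes two
#' sites to per-kb levels -- the two summaries answer different questions.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param calls tibble with `chrom`, `pos`, `strand`, `is_methylated`.
#' @param regions optional tibble `chrom`, `start`, `end`; whole genome
#'   when `NULL`.
#' @return fraction in `[0, 1]`, or `NA` if the regions hold no CpG.
#' @export
cpg_site_methylation_fraction <- function(genome, calls, regions = NULL) {
  stopifnot_fields(calls, c("chrom", "pos", "strand", "is_methylated"),
                   "calls")
  dinucs <- list()
  for (cn in names(genome)) {
    hits <- Biostrings::start(Biostrings::matchPattern("CG", genome[[cn]]))
    if (length(hits) > 0) dinucs[[cn]] <- tibble(chrom = cn, pos = hits)
  }
  if (length(dinucs) == 0) return(NA_real_)
  d <- bind_rows(dinucs)
  if (!is.null(regions)) {
    d <- d[positions_in_intervals(d, regions), , drop = FALSE]
  }
  if (nrow(d) == 0) return(NA_real_)
  m <- calls[calls$is_methylated, , drop = FALSE]
  key_plus <- paste(m$chrom[m$strand == "+"], m$pos[m$strand == "+"])
  key_minus <- paste(m$chrom[m$strand == "-"], m$pos[m$strand == "-"])
  hit <- paste(d$chrom, d$pos) %in% key_plus |
    paste(d$chrom, d$pos + 1L) %in% key_minus
  mean(hit)
}
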