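## Integration of RIP, methylation and expression evidence on TEs.

TE_SUPERFAMILIES <- c("LINE", "LTR", "DIRS", "PLE", "TIR", "helitron",
                      "MITE", "unclassified")

#' Flag transposable-element expression from filtered RNA-seq alignments
#'
#' Reads are kept when they map with at most `max_mismatches` mismatches
#' and at most `max_hits` genomic hits (multi-mappers are filtered); a TE
#' is expressed iff at least `min_reads` surviving reads overlap it.
#' Mate-pair concordance is an alignment-time property and is assumed to
#' have been enforced upstream of the BED6+2 input.
#'
#' @param te_features tibble of TE intervals with `ID`, `chrom`, `start`,
#'   `end`.
#' @param rnaseq BED6+2 tibble with `mismatches` and `hits` columns (see
#'   [read_bed6()] with `extended = TRUE`).
#' @param max_mismatches maximum mismatches per read (default 2).
#' @param max_hits maximum genomic hits (default 1 = unique mappers only).
#' @param min_reads minimum surviving overlapping reads (default 1).
#' @return tibble: `te_id`, `n_reads`, `expressed`.
#' @export
flag_te_expression <- function(te_features, rnaseq, max_mismatches = 2,
                               max_hits = 1, min_reads = 1) {
  stopifnot_fields(te_features, c("ID", "chrom", "start", "end"),
                   "te_features")
  if (!all(c("mismatches", "hits") %in% names(rnaseq))) {
    abort(paste0("flag_te_expression: alignments lack the 'mismatches'/",
                 "'hits' extension columns (read with read_bed6(path, ",
                 "extended = TRUE))"))
  }
  keep <- rnaseq[rnaseq$mismatches <= max_mismatches &
                   rnaseq$hits <= max_hits, , drop = FALSE]
  fgr <- GenomicRanges::GRanges(te_features$chrom,
                                IRanges::IRanges(te_features$start,
                                                 te_features$end))
  n <- if (nrow(keep) == 0) {
    rep(0L, nrow(te_features))
  } else {
    rgr <- GenomicRanges::GRanges(keep$chrom,
                                  IRanges::IRanges(keep$start, keep$end))
    GenomicRanges::countOverlaps(fgr, rgr)
  }
  tibble(te_id = te_features$ID, n_reads = as.integer(n),
         expressed = n >= min_reads)
}

#' Assemble per-TE activity records
#'
#' Combines expression flags with RIP and methylation evidence: a TE is
#' RIP-affected when at least `min_rip` called RIP sites fall inside its
#' interval, and methylated when at least `min_mc` methylated cytosines
#' do.
#'
#' @param te_features TE tibble with `ID`, `chrom`, `start`, `end`,
#'   `te_class`, `superfamily`.
#' @param expression output of [flag_te_expression()] (or any tibble with
#'   `te_id`, `expressed`).
#' @param rip_sites tibble with `chrom`, `pos` of called RIP sites.
#' @param methyl_calls tibble with `chrom`, `pos`, `is_methylated`.
#' @param min_rip,min_mc per-TE evidence minima (default 1 site each).
#' @return tibble: `te_id`, `te_class`, `superfamily`, `expressed`,
#'   `rip_affected`, `methylated`.
#' @export
te_activity_records <- function(te_features, expression, rip_sites,
                                methyl_calls, min_rip = 1, min_mc = 1) {
  stopifnot_fields(te_features,
                   c("ID", "chrom", "start", "end", "te_class",
                     "superfamily"), "te_features")
  bad <- !te_features$superfamily %in% TE_SUPERFAMILIES
  if (any(bad)) {
    abort(paste0("unknown superfamily: ",
                 paste(unique(te_features$superfamily[bad]), collapse = ", ")))
  }
  implied <- SUPERFAMILY_CLASS[te_features$superfamily]
  mismatch <- !is.na(implied) & implied != te_features$te_class
  if (any(mismatch)) {
    abort("te_activity_records: superfamily inconsistent with te_class")
  }
  fgr <- GenomicRanges::GRanges(te_features$chrom,
                                IRanges::IRanges(te_features$start,
                                                 te_features$end))
  count_at <- function(events) {
    if (is.null(events) || nrow(events) == 0) return(rep(0L, nrow(te_features)))
    gr <- GenomicRanges::GRanges(events$chrom,
                                 IRanges::IRanges(events$pos, events$pos))
    GenomicRanges::countOverlaps(fgr, gr)
  }
  mc <- methyl_calls
  if (!is.null(mc) && "is_methylated" %in% names(mc)) {
    mc <- mc[mc$is_methylated, , drop = FALSE]
  }
  tibble(
    te_id = te_features$ID,
    te_class = te_features$te_class,
    superfamily = te_features$superfamily,
    expressed = te_features$ID %in% expression$te_id[expression$expressed],
    rip_affected = count_at(rip_sites) >= min_rip,
    methylated = count_at(mc) >= min_mc
  )
}

CROSSTAB_SETS <- c("Total", "RIP", "Non-RIP", "5mC", "Non-5mC",
                   "RIP & 5mC", "Non-RIP & non-5mC")

#' Cross-tabulate TE activity against RIP and methylation status
#'
#' Builds the classic TE-silencing table: for each evidence set (`Total`,
#' `RIP`, `Non-RIP`, `5mC`, `Non-5mC`, `RIP & 5mC`, `Non-RIP & non-5mC`)
#' crossed with expression status, the record count (`num`) and, per
#' superfamily, the percentage relative to the grand total of records.
#' Percentages are kept at full precision internally (so partition
#' identities hold exactly) and rounded half-up to 2 decimals by
#' `format()`/[tidy()].
#'
#' @param records tibble from [te_activity_records()].
#' @return object of class `te_crosstab`: a tibble with `te_set`,
#'   `expressed`, `num` and one percentage column per superfamily;
#'   `n_records` is stored as an attribute.
#' @export
crosstab <- function(records) {
  stopifnot_fields(records,
                   c("te_id", "te_class", "superfamily", "expressed",
                     "rip_affected", "methylated"), "records")
  total <- nrow(records)
  sets <- list(
    "Total" = rep(TRUE, total),
    "RIP" = records$rip_affected,
    "Non-RIP" = !records$rip_affected,
    "5mC" = records$methylated,
    "Non-5mC" = !records$methylated,
    "RIP & 5mC" = records$rip_affected & records$methylated,
    "Non-RIP & non-5mC" = !records$rip_affected & !records$methylated
  )
  rows <- list()
  for (set_name in names(sets)) {
    for (exp_flag in c(TRUE, FALSE)) {
      sel <- sets[[set_name]] & records$expressed == exp_flag
      row <- tibble(te_set = set_name,
                    expressed = ifelse(exp_flag, "Yes", "No"),
                    num = sum(sel))
      for (sf in TE_SUPERFAMILIES) {
        row[[sf]] <- if (total > 0) {
          sum(sel & records$superfamily == sf) / total * 100
        } else NA_real_
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- bind_rows(rows)
  attr(out, "n_records") <- total
  class(out) <- c("te_crosstab", class(out))
  out
}

#' @export
print.te_crosstab <- function(x, ...) {
  cat("<te_crosstab> ", attr(x, "n_records"),
      " TE records; cells are % of all records\n", sep = "")
  y <- as_tibble(x)
  for (sf in intersect(TE_SUPERFAMILIES, names(y))) {
    y[[sf]] <- round_half_up(y[[sf]], 2)
  }
  print(y)
  invisible(x)
}

#' Silencing fraction of class I TEs under a condition
#'
#' Among class I (retrotransposon) records matching `condition`, the
#' fraction that are *not* expressed -- e.g. the fraction of RIP'd and
#' methylated retrotransposons that are silenced.
#'
#' @param records tibble from [te_activity_records()].
#' @param condition an unquoted logical expression in the record columns
#'   (default: `rip_affected & methylated`).
#' @return fraction in `[0, 1]`; `NA` when no class I record matches.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   te_id = as.character(1:4), te_class = "I", superfamily = "LTR",
#'   expressed = c(FALSE, FALSE, TRUE, FALSE),
#'   rip_affected = TRUE, methylated = c(TRUE, TRUE, TRUE, FALSE)
#' )
#' silencing_fraction(rec)
silencing_fraction <- function(records,
                               condition = rip_affected & methylated) {
  cond <- eval_tidy(enquo(condition), data = records)
  sel <- records$te_class == "I" & cond
  if (!any(sel)) return(NA_real_)
  mean(!records$expressed[sel])
}

#' Detect joint RIP/methylation-rich defense regions
#'
#' A window qualifies when all four hallmarks hold: GC fraction at most
#' `gc_max`, CRI at least `cri_min`, and at least `rip_min` RIP sites and
#' `mc_min` methylated cytosines.  Runs of at least `min_windows`
#' consecutive qualifying windows are merged into regions.
#'
#' Data-derived defaults (declared configuration, not inferred values):
#' `gc_max` = mean window GC minus one SD, `cri_min` = 0, `rip_min` and
#' `mc_min` = the 90th percentile of nonzero window counts.
#'
#' @param tracks window tibble from [windowed_tracks()].
#' @param gc_max,cri_min,rip_min,mc_min window thresholds (see above).
#' @param min_windows minimum run length of qualifying windows.
#' @return tibble of regions: `chrom`, `start`, `end`, `n_windows`, and
#'   the four threshold flags (all `TRUE` by construction).
#' @export
detect_defense_regions <- function(tracks, gc_max = NULL, cri_min = 0,
                                   rip_min = NULL, mc_min = NULL,
                                   min_windows = 5) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_windows = integer(), low_gc = logical(),
                  high_cri = logical(), rip_enriched = logical(),
                  mc_enriched = logical())
  if (nrow(tracks) == 0) return(empty)
  gc_max <- gc_max %||%
    (mean(tracks$gc_fraction) - sd(tracks$gc_fraction))
  p90 <- function(x) {
    x <- x[x > 0]
    if (length(x) == 0) Inf else as.numeric(quantile(x, 0.9))
  }
  rip_min <- rip_min %||% p90(tracks$rip_site_count)
  mc_min <- mc_min %||% p90(tracks$mc_count)
  q <- tracks$gc_fraction <= gc_max &
    !is.na(tracks$cri) & tracks$cri >= cri_min &
    tracks$rip_site_count >= rip_min &
    tracks$mc_count >= mc_min
  out <- list()
  for (cn in unique(tracks$chrom)) {
    idx <- which(tracks$chrom == cn)
    runs <- rle(q[idx])
    pos <- cumsum(c(1, runs$lengths))
    for (r in seq_along(runs$lengths)) {
      if (!runs$values[r] || runs$lengths[r] < min_windows) next
      wins <- idx[pos[r]:(pos[r + 1] - 1)]
      out[[length(out) + 1]] <- tibble(
        chrom = cn, start = min(tracks$start[wins]),
        end = max(tracks$end[wins]), n_windows = length(wins),
        low_gc = TRUE, high_cri = TRUE, rip_enriched = TRUE,
        mc_enriched = TRUE
      )
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}
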