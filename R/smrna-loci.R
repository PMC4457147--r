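## Small-RNA locus discovery and milRNA / disiRNA classification.

## per-alignment read weight under the chosen multi-mapper policy
multimap_weights <- function(aln, multimap) {
  hits <- ave(rep(1L, nrow(aln)), aln$name, FUN = sum)
  switch(multimap,
         fractional = aln$score / hits,
         all = aln$score,
         unique = ifelse(hits > 1, 0, aln$score))
}

#' Scan strand-specific small-RNA alignments for candidate loci
#'
#' Reads on either strand closer than `max_gap` are merged into one locus;
#' loci below `min_density` reads/kb, or supported by fewer than
#' `min_reads` reads, are discarded.  Density is computed over the merged
#' interval length.  Multi-mapped reads (same `name` on several records)
#' contribute `1/hits` each under the default `fractional` policy.
#'
#' @param alignments BED6 tibble (`chrom`, `start`, `end`, `name`, `score`
#'   = collapsed copy count, `strand`), sorted by chrom then start.
#' @param min_density minimum locus density in reads/kb (default 60, the
#'   disiRNA screening floor; milRNA candidates are re-thresholded by
#'   [call_milrna()]).
#' @param max_gap maximum gap (bp) between reads merged into one locus.
#' @param min_reads minimum weighted read support per locus; guards
#'   against chance pile-ups of a couple of background reads whose tiny
#'   span would otherwise pass a pure density threshold.
#' @param multimap `"fractional"`, `"all"` or `"unique"`.
#' @return tibble of candidate loci: `chrom`, `start`, `end`, `length`,
#'   `plus_reads`, `minus_reads`, `n_reads`, `density` (reads/kb),
#'   `strand_ratio` (max/min strand counts, `Inf` when one strand is
#'   empty), `dominant_strand`, `class` (initialised to `"none"`).
#' @export
scan_loci <- function(alignments, min_density = 60, max_gap = 50,
                      min_reads = 10,
                      multimap = c("fractional", "all", "unique")) {
  multimap <- match.arg(multimap)
  stopifnot_fields(alignments,
                   c("chrom", "start", "end", "name", "score", "strand"),
                   "alignments")
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), plus_reads = numeric(),
                  minus_reads = numeric(), n_reads = numeric(),
                  density = numeric(), strand_ratio = numeric(),
                  dominant_strand = character(), class = character())
  if (nrow(alignments) == 0) return(empty)
  o <- order(alignments$chrom, alignments$start)  # stable, so sorted input
  if (any(o != seq_along(o))) {                   # gives the identity
    abort("scan_loci: alignments must be sorted by chrom, start (use arrange())")
  }
  aln <- alignments
  aln$w <- multimap_weights(aln, multimap)
  out <- list()
  for (cn in unique(aln$chrom)) {
    x <- aln[aln$chrom == cn, ]
    run_end <- cummax(x$end)
    new_locus <- c(TRUE, x$start[-1] > run_end[-nrow(x)] + max_gap)
    grp <- cumsum(new_locus)
    loci <- x |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(
        chrom = cn, start = min(.data$start), end = max(.data$end),
        plus_reads = sum(.data$w[.data$strand == "+"]),
        minus_reads = sum(.data$w[.data$strand == "-"]),
        .groups = "drop"
      ) |>
      select(-"grp")
    out[[length(out) + 1]] <- loci
  }
  loci <- bind_rows(out) |>
    mutate(
      length = .data$end - .data$start + 1L,
      n_reads = .data$plus_reads + .data$minus_reads,
      density = .data$n_reads / (.data$length / 1000),
      strand_ratio = pmax(.data$plus_reads, .data$minus_reads) /
        pmin(.data$plus_reads, .data$minus_reads),
      dominant_strand = ifelse(.data$plus_reads >= .data$minus_reads,
                               "+", "-"),
      class = "none"
    ) |>
    filter(.data$density >= min_density, .data$n_reads >= min_reads) |>
    select("chrom", "start", "end", "length", "plus_reads", "minus_reads",
           "n_reads", "density", "strand_ratio", "dominant_strand",
           "class") |>
    arrange(.data$chrom, .data$start)
  loci
}

#' Classify candidate loci as milRNA
#'
#' A locus is a milRNA locus iff, evaluated in order:
#' \enumerate{
#'   \item reads derive significantly from one strand (ratio >=
#'     `strand_fold`; a zero minority strand counts as infinite ratio);
#'   \item read density exceeds `min_density` reads/kb;
#'   \item the precursor (locus extended by `flank` bp each side, on the
#'     dominant strand) folds with MFE <= `mfe_max` kcal/mol and
#'     MFEI > `mfei_min`;
#'   \item the mature candidate -- the most abundant 18-25 nt read in the
#'     locus -- sits on the hairpin stem (every mature base paired or in
#'     unpaired interruptions of at most 2 nt).
#' }
#'
#' @param loci candidate tibble from [scan_loci()].
#' @param alignments the BED6 alignments the loci were scanned from; a
#'   `seq` column supplies read sequences, otherwise they are extracted
#'   from the genome.
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank precursor flank in bp on each side (default 80).
#' @param min_density milRNA density threshold in reads/kb (default 270).
#' @param strand_fold minimum strand-bias fold (default 10).
#' @param mfe_max maximum (most positive acceptable) MFE in kcal/mol.
#' @param mfei_min minimum MFEI.
#' @param backend folding backend for [fold_rna()].
#' @return `loci` with `class` set to `"milRNA"` where accepted, plus
#'   hairpin-evaluation columns: `mature_seq`, `mfe`, `gc_percent`,
#'   `mfei`, `mature_on_stem`, `fail_reason` (`NA` for accepted loci).
#' @export
call_milrna <- function(loci, alignments, genome, flank = 80,
                        min_density = 270, strand_fold = 10,
                        mfe_max = -20, mfei_min = 0.8,
                        backend = c("stack", "rnafold")) {
  backend <- match.arg(backend)
  n <- nrow(loci)
  loci$mature_seq <- NA_character_
  loci$mfe <- NA_real_
  loci$gc_percent <- NA_real_
  loci$mfei <- NA_real_
  loci$mature_on_stem <- NA
  loci$fail_reason <- NA_character_
  if (n == 0) return(loci)
  chrom_len <- setNames(Biostrings::width(genome), names(genome))
  for (i in seq_len(n)) {
    lc <- loci[i, ]
    ## criterion 1: strand bias
    if (!(is.infinite(lc$strand_ratio) || lc$strand_ratio >= strand_fold)) {
      loci$fail_reason[i] <- "strand_ratio"
      next
    }
    ## criterion 2: density
    if (!(lc$density > min_density)) {
      loci$fail_reason[i] <- "density"
      next
    }
    ## criterion 4: precursor thermodynamics
    p_start <- max(1L, lc$start - as.integer(flank))
    p_end <- min(chrom_len[[lc$chrom]], lc$end + as.integer(flank))
    prec <- as.character(Biostrings::subseq(genome[[lc$chrom]],
                                            p_start, p_end))
    if (lc$dominant_strand == "-") prec <- revcomp_chr(prec)
    fold <- fold_rna(prec, backend = backend)
    gc_pct <- mean(chars(prec) %in% c("G", "C")) * 100
    loci$mfe[i] <- fold$mfe
    loci$gc_percent[i] <- gc_pct
    loci$mfei[i] <- mfei(fold$mfe, nchar(prec), gc_pct)
    if (!(fold$mfe <= mfe_max && loci$mfei[i] > mfei_min)) {
      loci$fail_reason[i] <- "mfe_mfei"
      next
    }
    ## criterion 3: mature candidate on the stem
    mature <- locus_mature_read(lc, alignments, genome)
    if (is.null(mature)) {
      loci$fail_reason[i] <- "no_mature_read"
      next
    }
    loci$mature_seq[i] <- mature$seq
    if (lc$dominant_strand == "+") {
      m_lo <- mature$start - p_start + 1L
      m_hi <- mature$end - p_start + 1L
    } else {
      m_lo <- p_end - mature$end + 1L
      m_hi <- p_end - mature$start + 1L
    }
    on_stem <- mature_on_stem(fold$partner, m_lo, m_hi)
    loci$mature_on_stem[i] <- on_stem
    if (!on_stem) {
      loci$fail_reason[i] <- "mature_off_stem"
      next
    }
    loci$class[i] <- "milRNA"
  }
  loci
}

## most abundant 18-25 nt read overlapping a locus, on its dominant strand
locus_mature_read <- function(locus, alignments, genome) {
  x <- alignments |>
    filter(.data$chrom == locus$chrom, .data$strand == locus$dominant_strand,
           .data$start <= locus$end, .data$end >= locus$start,
           .data$end - .data$start + 1L >= 18,
           .data$end - .data$start + 1L <= 25)
  if (nrow(x) == 0) return(NULL)
  x <- x[which.max(x$score), ]
  sq <- if ("seq" %in% names(x)) {
    x$seq
  } else {
    s <- as.character(Biostrings::subseq(genome[[x$chrom]], x$start, x$end))
    if (x$strand == "-") revcomp_chr(s) else s
  }
  list(seq = sq, start = x$start, end = x$end)
}

## every mature base paired, allowing unpaired interruptions <= 2 nt
mature_on_stem <- function(partner, lo, hi) {
  if (lo < 1 || hi > length(partner) || lo > hi) return(FALSE)
  paired <- partner[lo:hi] > 0
  if (!any(paired)) return(FALSE)
  runs <- rle(paired)
  all(runs$lengths[!runs$values] <= 2)
}

#' Classify candidate loci as disiRNA
#'
#' A locus is a disiRNA locus iff reads come from both strands in similar
#' abundance (`strand_ratio <= balance_max`), its density reaches
#' `min_density` reads/kb, and it was not already classified as milRNA.
#'
#' @param loci tibble from [scan_loci()] (typically after
#'   [call_milrna()]).
#' @param balance_max maximum strand ratio treated as "similar abundance"
#'   (default 2; the criterion is qualitative in the literature, so the
#'   operational threshold is explicit configuration).
#' @param min_density minimum density in reads/kb (default 60).
#' @return `loci` with `class` set to `"disiRNA"` where accepted.
#' @export
call_disirna <- function(loci, balance_max = 2, min_density = 60) {
  if (nrow(loci) == 0) return(loci)
  hit <- loci$class != "milRNA" &
    !is.infinite(loci$strand_ratio) &
    loci$strand_ratio <= balance_max &
    loci$density >= min_density
  loci$class[hit] <- "disiRNA"
  loci
}

#' Scan and classify small-RNA loci in one step
#'
#' Convenience wrapper: [scan_loci()], then [call_milrna()], then
#' [call_disirna()].
#'
#' @inheritParams scan_loci
#' @inheritParams call_milrna
#' @param balance_max maximum disiRNA strand ratio.
#' @param min_density_mil,min_density_disi class-specific density
#'   thresholds in reads/kb.
#' @return classified locus tibble.
#' @export
classify_loci <- function(alignments, genome, min_density_mil = 270,
                          min_density_disi = 60, strand_fold = 10,
                          mfe_max = -20, mfei_min = 0.8, flank = 80,
                          balance_max = 2, max_gap = 50, min_reads = 10,
                          multimap = "fractional",
                          backend = c("stack", "rnafold")) {
  loci <- scan_loci(alignments, min_density = min_density_disi,
                    max_gap = max_gap, min_reads = min_reads,
                    multimap = multimap)
  loci <- call_milrna(loci, alignments, genome, flank = flank,
                      min_density = min_density_mil,
                      strand_fold = strand_fold, mfe_max = mfe_max,
                      mfei_min = mfei_min, backend = backend)
  call_disirna(loci, balance_max = balance_max,
               min_density = min_density_disi)
}
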