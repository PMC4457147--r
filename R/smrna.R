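## Small-RNA library summaries: collapsing, partitioning, abundance, bias.

#' Collapse a read library into unique sequences
#'
#' Exact-sequence collapsing with no mismatch tolerance; total read counts
#' are preserved.
#'
#' @param reads character vector of read sequences, or a tibble with
#'   `sequence` (and optional `count`) columns.
#' @return tibble `sequence`, `count`, sorted by decreasing count.
#' @export
#' @examples
#' collapse_unique(c("AC", "AC", "GT"))
collapse_unique <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot_fields(reads, "sequence", "reads")
    if (!"count" %in% names(reads)) reads$count <- 1L
    tab <- reads |>
      group_by(.data$sequence) |>
      summarise(count = sum(.data$count), .groups = "drop")
  } else {
    if (length(reads) == 0) {
      return(tibble(sequence = character(), count = integer()))
    }
    t0 <- table(reads)
    tab <- tibble(sequence = names(t0), count = as.integer(t0))
  }
  arrange(tab, desc(.data$count), .data$sequence)
}

#' Summarise a two-way partition of unique sequences
#'
#' Given the number of sequences shared between two libraries and the
#' number specific to each, reports the union total and percentages
#' (rounded half-up to 2 decimals, the convention used for published
#' library comparisons).
#'
#' @param n_shared,n_a_only,n_b_only unique-sequence counts per class.
#' @return tibble with rows `shared`, `a_only`, `b_only`: `n`, `pct`; the
#'   union size is in the `total` attribute.
#' @export
#' @examples
#' partition_percentages(65362, 554521, 1035653)
partition_percentages <- function(n_shared, n_a_only, n_b_only) {
  total <- n_shared + n_a_only + n_b_only
  out <- tibble(
    category = c("shared", "a_only", "b_only"),
    n = as.integer(c(n_shared, n_a_only, n_b_only)),
    pct = if (total > 0) {
      round_half_up(c(n_shared, n_a_only, n_b_only) / total * 100, 2)
    } else rep(NA_real_, 3)
  )
  attr(out, "total") <- as.integer(total)
  out
}

#' Partition the unique sequences of two libraries
#'
#' Splits the union of unique sequences into shared, a-specific and
#' b-specific classes.
#'
#' @param table_a,table_b unique-sequence tables from [collapse_unique()].
#' @return as [partition_percentages()]; the three classes are disjoint
#'   and their counts sum to the union size.
#' @export
partition_libraries <- function(table_a, table_b) {
  a <- unique(table_a$sequence)
  b <- unique(table_b$sequence)
  shared <- length(intersect(a, b))
  partition_percentages(shared, length(a) - shared, length(b) - shared)
}

#' Filter reads by length
#'
#' Inclusive bounds; the 18-30 nt defaults match the mappable small-RNA
#' size range.
#'
#' @param reads character vector, or tibble with a `sequence` column.
#' @param min,max inclusive length bounds in nt.
#' @return the reads whose length lies in `[min, max]`.
#' @export
length_filter <- function(reads, min = 18, max = 30) {
  if (is.data.frame(reads)) {
    stopifnot_fields(reads, "sequence", "reads")
    keep <- nchar(reads$sequence) >= min & nchar(reads$sequence) <= max
    return(reads[keep, , drop = FALSE])
  }
  reads[nchar(reads) >= min & nchar(reads) <= max]
}

#' Transcripts-per-million normalisation
#'
#' `tpm_i = count_i / sum(count) * 1e6`; the values sum to one million.
#'
#' @param counts nonnegative numeric vector of read counts.
#' @return numeric vector of TPM values.
#' @export
#' @examples
#' tpm(c(1, 3))
tpm <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) return(rep(NA_real_, length(counts)))
  counts / sum(counts) * 1e6
}

#' 5'-terminal nucleotide bias
#'
#' Fraction of reads starting with each nucleotide (T is reported as U,
#' following small-RNA convention).
#'
#' @param reads character vector of read sequences, or a
#'   [collapse_unique()] table (counts are then used as weights).
#' @return tibble `nt`, `n`, `fraction` over `{A, C, G, U}`; zero rows for
#'   empty input.
#' @export
five_prime_bias <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot_fields(reads, "sequence", "reads")
    seqs <- reads$sequence
    wts <- if ("count" %in% names(reads)) reads$count else rep(1L, nrow(reads))
  } else {
    seqs <- reads
    wts <- rep(1L, length(reads))
  }
  if (length(seqs) == 0) {
    return(tibble(nt = character(), n = integer(), fraction = numeric()))
  }
  first <- chartr("T", "U", toupper(substr(seqs, 1, 1)))
  tibble(nt = first, w = wts) |>
    group_by(.data$nt) |>
    summarise(n = sum(.data$w), .groups = "drop") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}
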