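## RIP detection: pre-RIP consensus, site calling, spectrum, preference.

#' Infer the pre-RIP state of a repeat family
#'
#' The ancestral (pre-RIP) sequence is modelled as the per-column majority
#' base with ties broken toward C/G over T/A: RIP only ever converts C to T
#' (G to A on the other strand), so where the column is ambiguous the
#' GC-richer state is ancestral.  A gap is emitted only where gaps hold a
#' strict majority.  The `"highest-gc"` model instead takes the copy with
#' the highest ungapped GC fraction as the pre-RIP reference.
#'
#' @param gapped character vector of >= 2 equal-length gapped sequences.
#' @param model `"consensus"` (default) or `"highest-gc"`.
#' @return the consensus as a single gapped string.
#' @export
#' @examples
#' build_consensus(c("ACGT", "ATGT", "ACGT"))
build_consensus <- function(gapped, model = c("consensus", "highest-gc")) {
  model <- match.arg(model)
  if (length(gapped) < 2) {
    abort("build_consensus: at least 2 copies are required")
  }
  if (length(unique(nchar(gapped))) != 1) {
    abort("build_consensus: gapped copies must have equal length")
  }
  if (model == "highest-gc") {
    gc <- vapply(gapped, function(s) {
      b <- chars(s)
      b <- b[b != "-"]
      mean(b %in% c("G", "C"))
    }, numeric(1))
    return(gapped[[which.max(gc)]])
  }
  mat <- do.call(rbind, strsplit(gapped, "", fixed = TRUE))
  n <- nrow(mat)
  pref <- c("C", "G", "A", "T")           # GC-ward tie-break order
  apply(mat, 2, function(col) {
    n_gap <- sum(col == "-")
    if (n_gap > n / 2) return("-")
    bases <- col[col %in% DNA_BASES]
    if (length(bases) == 0) return("-")
    cnt <- table(factor(bases, levels = pref))
    names(cnt)[which.max(cnt)]            # which.max honours `pref` order
  }) |> paste(collapse = "")
}

#' Call RIP sites in a repeat-family alignment
#'
#' A site is emitted for every alignment column where the consensus carries
#' the ancestral C and a copy carries the derived T (read in the alignment
#' orientation), or consensus G / copy A -- a C-to-T transition on the
#' opposite strand.  The ancestral dinucleotide context is the consensus C
#' plus its 3' neighbour *on the affected strand*; columns whose neighbour
#' is an alignment gap (or off the end) are skipped.  Each copy contributes
#' an independent event, so a column mutated in three copies yields three
#' sites.
#'
#' @param family a [repeat_family()].
#' @return tibble of sites: `family_id`, `copy_id`, `column` (alignment
#'   column), `copy_pos` (1-based ungapped position on the copy), `chrom`,
#'   `pos` (plus-strand genome coordinate of the affected C, `NA` when the
#'   copy has no genome interval), `strand` (affected strand), `context`
#'   (`CpA`/`CpC`/`CpG`/`CpT`), `ref`, `obs`.
#' @export
call_rip_sites <- function(family) {
  stopifnot(inherits(family, "repeat_family"))
  cc <- chars(family$consensus)
  L <- length(cc)
  copies <- family$copies
  mat <- do.call(rbind, strsplit(copies$seq, "", fixed = TRUE))
  out <- list()
  for (i in seq_len(nrow(copies))) {
    row <- mat[i, ]
    offset <- cumsum(row != "-")          # ungapped position per column
    ## C -> T on the alignment strand
    ct <- which(cc == "C" & row == "T")
    ct <- ct[ct < L & cc[pmin(ct + 1L, L)] %in% DNA_BASES]
    ## G -> A: C -> T on the opposite strand
    ga <- which(cc == "G" & row == "A")
    ga <- ga[ga > 1L & cc[pmax(ga - 1L, 1L)] %in% DNA_BASES]
    if (length(ct) + length(ga) == 0) next
    col <- c(ct, ga)
    same <- rep(c(TRUE, FALSE), c(length(ct), length(ga)))
    ctx <- c(if (length(ct)) paste0("Cp", cc[ct + 1L]) else character(0),
             if (length(ga)) paste0("Cp", complement_chr(cc[ga - 1L]))
             else character(0))
    strand0 <- copies$strand[i]
    gstrand <- ifelse(same, strand0, flip_strand(strand0))
    o <- offset[col]
    gpos <- if (is.na(copies$start[i])) {
      rep(NA_integer_, length(col))
    } else if (strand0 == "+") {
      copies$start[i] + o - 1L
    } else {
      copies$end[i] - o + 1L
    }
    out[[length(out) + 1]] <- tibble(
      family_id = family$family_id, copy_id = copies$copy_id[i],
      column = as.integer(col), copy_pos = as.integer(o),
      chrom = copies$chrom[i], pos = as.integer(gpos), strand = gstrand,
      context = ctx, ref = "C", obs = "T"
    )
  }
  if (length(out) == 0) {
    return(tibble(family_id = character(), copy_id = character(),
                  column = integer(), copy_pos = integer(),
                  chrom = character(), pos = integer(), strand = character(),
                  context = character(), ref = character(),
                  obs = character()))
  }
  bind_rows(out) |> arrange(.data$copy_id, .data$column)
}

SPECTRUM_CLASSES <- c("CG>TA", "CG>AT", "CG>GC", "AT>GC", "AT>CG", "AT>TA")

classify_substitution <- function(ref, obs) {
  key <- paste0(ref, obs)
  map <- c(CT = "CG>TA", GA = "CG>TA",
           CA = "CG>AT", GT = "CG>AT",
           CG = "CG>GC", GC = "CG>GC",
           AG = "AT>GC", TC = "AT>GC",
           AC = "AT>CG", TG = "AT>CG",
           AT = "AT>TA", TA = "AT>TA")
  unname(map[key])
}

#' Mutation spectrum of repeat families
#'
#' Classifies *every* consensus-versus-copy substitution (not only RIP-like
#' C-to-T events) into the six strand-symmetric substitution classes and
#' reports the fraction of C:G->T:A transitions -- the RIP hallmark.  Each
#' copy-by-column event is counted once.
#'
#' @param families a `repeat_family` or list of them.
#' @return an object of class `mutation_spectrum` with elements `counts`
#'   (tibble `class`, `n`, `fraction`), `total`, and `fraction_CG_to_TA`
#'   (`NA` when no substitutions exist).
#' @export
mutation_spectrum <- function(families) {
  if (inherits(families, "repeat_family")) families <- list(families)
  events <- character(0)
  for (fam in families) {
    cc <- chars(fam$consensus)
    mat <- do.call(rbind, strsplit(fam$copies$seq, "", fixed = TRUE))
    for (i in seq_len(nrow(mat))) {
      row <- mat[i, ]
      sub <- which(cc %in% DNA_BASES & row %in% DNA_BASES & cc != row)
      if (length(sub) > 0) {
        events <- c(events, classify_substitution(cc[sub], row[sub]))
      }
    }
  }
  cnt <- table(factor(events, levels = SPECTRUM_CLASSES))
  total <- sum(cnt)
  counts <- tibble(
    class = SPECTRUM_CLASSES, n = as.integer(cnt),
    fraction = if (total > 0) as.integer(cnt) / total else NA_real_
  )
  structure(
    list(counts = counts, total = total,
         fraction_CG_to_TA = if (total > 0) {
           counts$fraction[counts$class == "CG>TA"]
         } else NA_real_),
    class = "mutation_spectrum"
  )
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("<mutation_spectrum> ", x$total, " substitution events\n", sep = "")
  if (x$total > 0) {
    cat("  C:G->T:A fraction: ", sprintf("%.3f", x$fraction_CG_to_TA),
        "\n", sep = "")
  }
  print(x$counts)
  invisible(x)
}

#' Dinucleotide preference of RIP sites
#'
#' @param rip_sites tibble of sites from [call_rip_sites()] (needs a
#'   `context` column).
#' @return tibble with one row per CpN context present: `context`, `n`,
#'   `fraction` (fractions sum to 1); zero rows for empty input.
#' @export
dinucleotide_preference <- function(rip_sites) {
  if (nrow(rip_sites) == 0) {
    return(tibble(context = character(), n = integer(),
                  fraction = numeric()))
  }
  rip_sites |>
    count(.data$context, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}
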