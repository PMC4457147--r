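## Repeat-family container and the built-in family aligner.

#' Construct a repeat-family alignment object
#'
#' @param copies tibble with one row per copy: `copy_id`, `seq` (gapped,
#'   equal length, written 5'->3' on the copy's own strand) and optionally
#'   `chrom`, `start`, `end`, `strand` genome coordinates.
#' @param family_id family identifier.
#' @param consensus optional pre-computed consensus; built with
#'   [build_consensus()] when `NULL`.
#' @param model consensus model passed to [build_consensus()].
#' @return an object of class `repeat_family`.
#' @export
repeat_family <- function(copies, family_id = "family",
                          consensus = NULL,
                          model = c("consensus", "highest-gc")) {
  model <- match.arg(model)
  stopifnot_fields(copies, c("copy_id", "seq"), "copies")
  if (!"strand" %in% names(copies)) copies$strand <- "+"
  for (f in c("chrom", "start", "end")) {
    if (!f %in% names(copies)) {
      copies[[f]] <- if (f == "chrom") NA_character_ else NA_integer_
    }
  }
  L <- unique(nchar(copies$seq))
  if (length(L) != 1) {
    abort("repeat_family: gapped copies must have equal length (align first)")
  }
  if (is.null(consensus)) consensus <- build_consensus(copies$seq, model)
  structure(
    list(family_id = family_id, copies = copies, consensus = consensus,
         column_count = L),
    class = "repeat_family"
  )
}

#' @export
print.repeat_family <- function(x, ...) {
  cat("<repeat_family> ", x$family_id, ": ", nrow(x$copies), " copies, ",
      x$column_count, " alignment columns\n", sep = "")
  invisible(x)
}

#' Align the copies of one repeat family (center-star progressive)
#'
#' Copies are aligned pairwise against the longest copy with
#' [Biostrings::pairwiseAlignment()] (match +1, mismatch -1, gap open -5,
#' gap extend -1) and the pairwise alignments are merged on the shared
#' center coordinates.  Equal-length ungapped input (e.g. simulator output,
#' or pre-aligned copies) is passed through untouched.
#'
#' @param seqs named character vector of ungapped copy sequences.
#' @return named character vector of gapped sequences of equal length.
#' @export
align_family <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("copy", seq_along(seqs))
  if (length(unique(nchar(seqs))) == 1) return(seqs)
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  others <- seqs[-center_i]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  Lc <- nchar(center)
  per <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(center),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 1
    )
    pat <- chars(as.character(Biostrings::alignedPattern(pa)))
    sub <- chars(as.character(Biostrings::alignedSubject(pa)))
    cpos <- cumsum(sub != "-")          # center position of each column
    is_ins <- sub == "-"
    slot <- ifelse(is_ins, cpos, cpos)  # insertions sit after center pos
    list(pat = pat, is_ins = is_ins, slot = slot)
  })
  ins <- integer(Lc + 1)                # max insertion length after pos 0..Lc
  for (p in per) {
    if (!any(p$is_ins)) next
    tab <- table(p$slot[p$is_ins])
    idx <- as.integer(names(tab)) + 1L
    ins[idx] <- pmax(ins[idx], as.integer(tab))
  }
  build_row <- function(p) {
    out <- character(0)
    for (c0 in 0:Lc) {
      block <- p$pat[p$is_ins & p$slot == c0]
      out <- c(out, block, rep("-", ins[c0 + 1] - length(block)))
      if (c0 < Lc) {
        out <- c(out, p$pat[!p$is_ins & p$slot == c0 + 1])
      }
    }
    paste(out, collapse = "")
  }
  center_row <- {
    out <- character(0)
    cc <- chars(center)
    for (c0 in 0:Lc) {
      out <- c(out, rep("-", ins[c0 + 1]))
      if (c0 < Lc) out <- c(out, cc[c0 + 1])
    }
    paste(out, collapse = "")
  }
  aligned <- c(setNames(center_row, names(seqs)[center_i]),
               setNames(vapply(per, build_row, character(1)), names(others)))
  aligned[names(seqs)]
}

## mean pairwise identity over columns where both copies have a base
mean_pairwise_identity <- function(gapped) {
  n <- length(gapped)
  if (n < 2) return(NA_real_)
  mats <- strsplit(gapped, "", fixed = TRUE)
  ids <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- mats[[i]]; b <- mats[[j]]
      both <- a != "-" & b != "-"
      if (!any(both)) next
      ids <- c(ids, mean(a[both] == b[both]))
    }
  }
  mean(ids)
}

#' Extract aligned repeat families from a genome and its TE annotations
#'
#' Applies the repeat inclusion rule used throughout the RIP analysis:
#' copies shorter than `min_length` are dropped, and families whose mean
#' pairwise identity falls below `min_identity` are excluded.  Copy
#' sequences are taken on the copy's own strand (minus-strand copies are
#' reverse-complemented) so that RIP events are read on the strand they
#' occurred on.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param features annotation tibble; TE rows have
#'   `type == "transposable_element"` and a `family_id`.
#' @param min_length minimum ungapped copy length (bp).
#' @param min_identity minimum mean pairwise identity.
#' @param model consensus model (see [build_consensus()]).
#' @return named list of `repeat_family` objects.
#' @export
extract_repeat_families <- function(genome, features, min_length = 400,
                                    min_identity = 0.80,
                                    model = c("consensus", "highest-gc")) {
  model <- match.arg(model)
  te <- features[features$type == "transposable_element", , drop = FALSE]
  te <- te[te$end - te$start + 1L >= min_length, , drop = FALSE]
  fams <- split(te, te$family_id)
  out <- list()
  for (fid in names(fams)) {
    f <- fams[[fid]]
    if (nrow(f) < 2) next
    seqs <- vapply(seq_len(nrow(f)), function(i) {
      s <- as.character(Biostrings::subseq(genome[[f$chrom[i]]],
                                           f$start[i], f$end[i]))
      if (f$strand[i] == "-") revcomp_chr(s) else s
    }, character(1))
    names(seqs) <- f$ID
    aligned <- align_family(seqs)
    pid <- mean_pairwise_identity(aligned)
    if (is.na(pid) || pid < min_identity) {
      inform(paste0("family '", fid, "' excluded: mean pairwise identity ",
                    sprintf("%.3f", pid), " < ", min_identity))
      next
    }
    copies <- tibble(copy_id = f$ID, chrom = f$chrom, start = f$start,
                     end = f$end, strand = f$strand,
                     seq = unname(aligned[f$ID]))
    out[[fid]] <- repeat_family(copies, family_id = fid, model = model)
  }
  out
}
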