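#' Fold an RNA (or DNA) sequence into its minimum-free-energy hairpin
#'
#' Two backends are available.  `"stack"` (the default) is the bundled
#' stacking-weighted maximum-pairing model compiled with the package; it is
#' deterministic and needs no external software.  `"rnafold"` shells out to
#' ViennaRNA's `RNAfold` when it is on the `PATH`.  Both return the minimum
#' free energy (MFE, kcal/mol) and a dot-bracket structure.
#'
#' @param seq a single sequence (DNA alphabet accepted; T is read as U).
#' @param backend `"stack"` or `"rnafold"`.
#' @return a list with elements `mfe` (kcal/mol, \eqn{\le 0}), `structure`
#'   (dot-bracket string) and `partner` (integer vector, 1-based pairing
#'   partner per position, 0 = unpaired; for the `"rnafold"` backend this is
#'   derived from the dot-bracket string).
#' @export
#' @examples
#' hp <- paste0(strrep("GC", 15), "GAAA", strrep("GC", 15))
#' fold_rna(hp)$mfe
fold_rna <- function(seq, backend = c("stack", "rnafold")) {
  backend <- match.arg(backend)
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (backend == "stack") {
    return(.fold_stack_cpp(seq))
  }
  if (Sys.which("RNAfold") == "") {
    abort(paste0("RNAfold not found on PATH; rerun with backend = \"stack\" ",
                 "to use the bundled folding model"))
  }
  out <- system2("RNAfold", c("--noPS"), input = chartr("T", "U", seq),
                 stdout = TRUE)
  line <- out[2]
  db <- sub("^([.()]+).*$", "\\1", line)
  mfe <- as.numeric(sub("^.*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(mfe = mfe, structure = db, partner = dotbracket_partners(db))
}

## partner vector from a dot-bracket string
dotbracket_partners <- function(db) {
  v <- chars(db)
  partner <- integer(length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  partner
}

#' Minimal folding free energy index (MFEI)
#'
#' `MFEI = AMFE / GC%`, where `AMFE = |MFE| / precursor length * 100` is the
#' length-adjusted MFE.  Values above ~0.8 distinguish miRNA-class hairpin
#' precursors from other structured RNAs.
#'
#' @param mfe minimum free energy in kcal/mol (\eqn{\le 0}).
#' @param precursor_length precursor length in nt.
#' @param gc_percent GC content of the precursor, in percent (0-100).
#' @return the MFEI (dimensionless, \eqn{\ge 0}); `NA` if `gc_percent` is 0.
#' @export
#' @examples
#' mfei(-40, 100, 50)  # exactly at the 0.8 decision boundary
mfei <- function(mfe, precursor_length, gc_percent) {
  stopifnot(all(mfe <= 0 | is.na(mfe)), all(precursor_length > 0))
  amfe <- abs(mfe) / precursor_length * 100
  ifelse(gc_percent > 0, amfe / gc_percent, NA_real_)
}
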