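#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule instead (2.345 -> 2.35 at 2 digits).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-")

## reverse complement of plain character strings (vectorised)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(unname(COMPLEMENT[strsplit(s, "", fixed = TRUE)[[1]]])),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_chr <- function(x) unname(COMPLEMENT[x])

## random sequence with a given GC fraction
random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

## strand flip
flip_strand <- function(s) ifelse(s == "+", "-", "+")

stopifnot_fields <- function(df, fields, what) {
  missing <- setdiff(fields, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

## fetch one chromosome as a character vector of bases
chrom_chars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome '", chrom, "' not found in genome"))
  }
  chars(as.character(genome[[chrom]]))
}

`%theni%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
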