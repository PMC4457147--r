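## Forward models of the strand-specific small-RNA and RNA-seq libraries.

#' Simulate strand-specific small-RNA alignments
#'
#' Each planted milRNA locus emits strand-biased reads clustered on a
#' mature window of its hairpin arm; disiRNA loci emit reads from both
#' strands uniformly across their interval; a uniform background is added
#' genome-wide at `background_read_rate` reads per kb.  Identical
#' alignments are collapsed (score = copy count), matching the BED6
#' dialect used throughout the package.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param loci planted-locus tibble as produced in
#'   `generate_genome()$truth$loci` (may have zero rows).
#' @param background_read_rate background reads per kb.
#' @param seed integer seed; identical inputs give identical output.
#' @return tibble of collapsed alignments: `chrom`, `start`, `end`, `name`,
#'   `score` (copy count), `strand`, `seq` (the read sequence, 5'->3').
#' @export
simulate_smrna <- function(genome, loci, background_read_rate = 2,
                           seed = 1L) {
  if (nrow(loci) > 0) {
    bad <- loci$start < 1 |
      loci$end > Biostrings::width(genome)[match(loci$chrom, names(genome))]
    if (any(bad | is.na(bad))) {
      abort("simulate_smrna: planted locus outside the genome")
    }
  }
  withr::with_seed(seed, {
    chrom_str <- setNames(as.character(genome), names(genome))
    chrom_len <- setNames(Biostrings::width(genome), names(genome))
    reads <- list()
    emit <- function(chrom, start, len, strand) {
      end <- start + len - 1L
      keep <- start >= 1L & end <= chrom_len[[chrom]]
      start <- start[keep]; end <- end[keep]; strand <- strand[keep]
      if (length(start) == 0) return(NULL)
      sq <- substring(chrom_str[[chrom]], start, end)
      sq[strand == "-"] <- revcomp_chr(sq[strand == "-"])
      tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = strand, seq = sq)
    }
    for (i in seq_len(nrow(loci))) {
      lc <- loci[i, ]
      lens_main <- function(n) {
        pmin(pmax(sample(c(21L, 22L, 22L, 22L, 23L, 24L), n, replace = TRUE),
                  lc$read_len_min), lc$read_len_max)
      }
      if (lc$class == "milRNA") {
        n <- lc$reads_fwd
        lens <- lens_main(n)
        jit <- sample(c(0L, 0L, 0L, 0L, 1L, -1L, 2L), n, replace = TRUE)
        if (lc$strand == "+") {
          starts <- lc$start + 2L + jit
        } else {
          starts <- lc$end - 2L - jit - lens + 1L
        }
        reads[[length(reads) + 1]] <- emit(lc$chrom, starts, lens,
                                           rep(lc$strand, n))
        m <- lc$reads_rev
        if (m > 0) {
          lens2 <- lens_main(m)
          starts2 <- as.integer(floor(runif(m, lc$start,
                                            pmax(lc$end - lens2 + 1,
                                                 lc$start) + 1)))
          reads[[length(reads) + 1]] <- emit(lc$chrom, starts2, lens2,
                                             rep(flip_strand(lc$strand), m))
        }
      } else {
        for (sd in c("+", "-")) {
          n <- if (sd == "+") lc$reads_fwd else lc$reads_rev
          if (n == 0) next
          lens <- lens_main(n)
          starts <- as.integer(floor(runif(n, lc$start,
                                           pmax(lc$end - lens + 1,
                                                lc$start) + 1)))
          reads[[length(reads) + 1]] <- emit(lc$chrom, starts, lens,
                                             rep(sd, n))
        }
      }
    }
    for (cn in names(genome)) {
      n_bg <- rpois(1, background_read_rate * chrom_len[[cn]] / 1000)
      if (n_bg == 0) next
      lens <- sample(19:28, n_bg, replace = TRUE)
      starts <- as.integer(floor(runif(n_bg, 1, chrom_len[[cn]] - lens)))
      reads[[length(reads) + 1]] <- emit(cn, starts, lens,
                                         sample(c("+", "-"), n_bg,
                                                replace = TRUE))
    }
    if (length(reads) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    name = character(), score = numeric(),
                    strand = character(), seq = character()))
    }
    bind_rows(reads) |>
      count(.data$chrom, .data$start, .data$end, .data$strand, .data$seq,
            name = "score") |>
      arrange(.data$chrom, .data$start, .data$end, .data$strand) |>
      mutate(name = sprintf("sr%05d", row_number()), score = .data$score) |>
      select("chrom", "start", "end", "name", "score", "strand", "seq")
  })
}

#' Simulate RNA-seq evidence of transposable-element expression
#'
#' Expressed TE copies receive uniquely-mapping reads with at most two
#' mismatches; a fraction of the silent copies receive only disqualified
#' reads (too many mismatches, or multi-mappers) so that the expression
#' filters have something to reject.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param te_copies TE-copy truth tibble (`te_id`, `chrom`, `start`, `end`,
#'   `strand`, `expressed`).
#' @param seed integer seed.
#' @param reads_per_te reads emitted per expressed copy.
#' @param read_len read length in bp.
#' @param decoy_frac fraction of silent copies receiving only
#'   filter-failing reads.
#' @return BED6+2 tibble: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `mismatches`, `hits`.
#' @export
simulate_rnaseq <- function(genome, te_copies, seed = 1L, reads_per_te = 5L,
                            read_len = 75L, decoy_frac = 0.3) {
  withr::with_seed(seed + 2L, {
    rows <- list()
    rid <- 0L
    for (i in seq_len(nrow(te_copies))) {
      te <- te_copies[i, ]
      len <- min(read_len, te$end - te$start + 1L)
      mk <- function(n, mismatches, hits) {
        starts <- as.integer(floor(runif(n, te$start,
                                         te$end - len + 1 + 1)))
        tibble(chrom = te$chrom, start = starts, end = starts + len - 1L,
               name = sprintf("rna%06d", rid + seq_len(n)), score = 1,
               strand = sample(c("+", "-"), n, replace = TRUE),
               mismatches = mismatches, hits = hits)
      }
      if (te$expressed) {
        out <- mk(reads_per_te, sample(0:2, reads_per_te, replace = TRUE), 1L)
      } else if (runif(1) < decoy_frac) {
        if (runif(1) < 0.5) {
          out <- mk(2L, 3L, 1L)       # too divergent (criterion 1)
        } else {
          out <- mk(2L, 0L, 3L)       # multi-mapper (criterion 3)
        }
      } else {
        next
      }
      rid <- rid + nrow(out)
      rows[[length(rows) + 1]] <- out
    }
    if (length(rows) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    name = character(), score = numeric(),
                    strand = character(), mismatches = integer(),
                    hits = integer()))
    }
    bind_rows(rows) |> arrange(.data$chrom, .data$start, .data$end)
  })
}
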