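#' Apply the RIP process to a set of repeat copies
#'
#' Forward model of repeat-induced point mutation: each eligible site (a C
#' with a 3' neighbour, read on the copy's own strand) is converted to T
#' with probability `rip_rate * w(context) / max(w)`, where `w` are the
#' CpN context weights.  The most-preferred context therefore mutates at
#' exactly `rip_rate`.
#'
#' To keep the planted truth identifiable by alignment against a majority
#' consensus, at most `floor(n/2)` copies may be mutated at any one column
#' (excess draws are discarded at random).  Without this cap a column could
#' lose its ancestral C in most copies, leaving no evidence of the
#' pre-mutation state.
#'
#' @param copies named character vector of ungapped, equal-length copy
#'   sequences (each written 5'->3' on its own strand).
#' @param rip_rate per-site mutation probability for the most-preferred
#'   context, in `[0, 1]`.
#' @param context_weights named nonnegative weights over `CpA`, `CpC`,
#'   `CpG`, `CpT`.
#' @param seed optional seed (the caller's RNG stream is used when `NULL`).
#' @return list with `copies` (mutated sequences) and `sites`, a tibble of
#'   planted events (`copy_id`, `pos` on the copy, `context`, `ref`, `obs`).
#' @export
#' @examples
#' set.seed(1)
#' out <- apply_rip(c(a = "ACGACGT", b = "ACGACGT"), 1,
#'                  c(CpA = 0, CpC = 0, CpG = 1, CpT = 0))
#' out$sites
apply_rip <- function(copies, rip_rate,
                      context_weights = c(CpA = 0.25, CpC = 0.10,
                                          CpG = 0.55, CpT = 0.10),
                      seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(is.character(copies), length(copies) >= 1)
  if (is.null(names(copies))) {
    names(copies) <- paste0("copy", seq_along(copies))
  }
  L <- unique(nchar(copies))
  if (length(L) != 1) abort("apply_rip: copies must have equal length")
  if (any(grepl("-", copies, fixed = TRUE))) {
    abort("apply_rip: copies must be ungapped")
  }
  empty_sites <- tibble(copy_id = character(), pos = integer(),
                        context = character(), ref = character(),
                        obs = character())
  if (rip_rate == 0 || L < 2) {
    return(list(copies = copies, sites = empty_sites))
  }
  w <- context_weights[c("CpA", "CpC", "CpG", "CpT")]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) abort("apply_rip: context weights must have sum > 0")
  wn <- w / max(w)
  names(wn) <- c("CpA", "CpC", "CpG", "CpT")

  n <- length(copies)
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  ctx_of <- c(A = "CpA", C = "CpC", G = "CpG", T = "CpT")
  sel <- matrix(FALSE, n, L)
  for (i in seq_len(n)) {
    b <- mat[i, ]
    elig <- which(b == "C")
    elig <- elig[elig < L]
    if (length(elig) == 0) next
    ctx <- unname(ctx_of[b[elig + 1]])
    p <- rip_rate * wn[ctx]
    p[is.na(p)] <- 0
    sel[i, elig[runif(length(elig)) < p]] <- TRUE
  }
  cap <- max(1L, floor(n / 2))  # a single copy is its own record
  over <- which(colSums(sel) > cap)
  for (j in over) {
    hits <- which(sel[, j])
    sel[sample(hits, length(hits) - cap), j] <- FALSE
  }
  idx <- which(sel, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(copies = copies, sites = empty_sites))
  sites <- tibble(
    copy_id = names(copies)[idx[, 1]],
    pos = as.integer(idx[, 2]),
    context = unname(ctx_of[mat[cbind(idx[, 1], idx[, 2] + 1L)]]),
    ref = "C", obs = "T"
  ) |> arrange(.data$copy_id, .data$pos)
  mat[sel] <- "T"
  mutated <- setNames(apply(mat, 1, paste, collapse = ""), names(copies))
  list(copies = mutated, sites = sites)
}

## non-overlapping interval placement with a safety margin
place_interval <- function(chrom_len, width, occupied, margin = 20L,
                           fixed_start = NA_integer_) {
  if (!is.na(fixed_start)) {
    if (fixed_start < 1 || fixed_start + width - 1 > chrom_len) {
      abort("planted feature does not fit inside the chromosome")
    }
    return(as.integer(fixed_start))
  }
  lo <- 1L + margin
  hi <- chrom_len - width - margin
  if (hi < lo) abort("chromosome too short for planted feature")
  for (try in 1:2000) {
    s <- as.integer(floor(runif(1, lo, hi + 1)))
    e <- s + width - 1L
    ok <- TRUE
    if (nrow(occupied) > 0) {
      ok <- all(e + margin < occupied$start | s - margin > occupied$end)
    }
    if (ok) return(s)
  }
  abort("could not place feature without overlap; reduce planted content")
}

#' Generate a synthetic genome with planted genome-defense ground truth
#'
#' Draws an i.i.d. background genome at the configured GC fraction, then
#' plants gene models (with exon/intron structure), repeat-family copies
#' carrying RIP mutations via [apply_rip()], and hairpin precursors for
#' milRNA loci (arms are redrawn until the bundled folding backend scores
#' the precursor at or below -20 kcal/mol).  Everything planted is recorded
#' in a ground-truth manifest.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `defense_sim`: a list with
#'   \describe{
#'     \item{genome}{[Biostrings::DNAStringSet] of chromosomes.}
#'     \item{features}{tibble of planted annotations (genes, exons, introns,
#'       TE copies), 1-based inclusive coordinates.}
#'     \item{truth}{list with `rip_sites`, `te_copies`, `loci` and the
#'       `expressed_te` id set.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_genome <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  withr::with_seed(cfg$seed, generate_genome_impl(cfg))
}

generate_genome_impl <- function(cfg) {
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom))
  chroms <- lapply(chrom_names, function(nm) {
    chars(random_seq(cfg$chrom_length, cfg$gc_background))
  })
  names(chroms) <- chrom_names
  occupied <- setNames(
    rep(list(tibble(start = integer(), end = integer())), cfg$n_chrom),
    chrom_names
  )
  features <- list()
  rip_truth <- list()
  te_truth <- list()
  loci_truth <- list()

  ## reserve fixed placements first so random features cannot collide
  for (spec in cfg$families) {
    if (is.na(spec$chrom)) next
    span <- spec$n_copies * (spec$unit_length + 151L)
    occupied[[spec$chrom]] <- add_row(occupied[[spec$chrom]],
                                      start = as.integer(spec$start),
                                      end = as.integer(spec$start) + span)
  }
  for (spec in cfg$smrna_loci) {
    if (is.na(spec$chrom) || is.na(spec$start)) next
    s <- as.integer(spec$start)
    if (spec$class == "milRNA") {
      occupied[[spec$chrom]] <- add_row(occupied[[spec$chrom]],
                                        start = s - 10L, end = s + 120L)
    } else {
      occupied[[spec$chrom]] <- add_row(occupied[[spec$chrom]],
                                        start = s, end = s + spec$length)
    }
  }

  ## --- gene models (background sequence is left untouched) -------------
  for (cn in chrom_names) {
    for (g in seq_len(cfg$n_genes)) {
      gid <- paste0("g_", cn, "_", g)
      glen <- cfg$gene_length
      s <- place_interval(cfg$chrom_length, glen, occupied[[cn]])
      occupied[[cn]] <- add_row(occupied[[cn]], start = s, end = s + glen - 1L)
      strand <- sample(c("+", "-"), 1)
      cuts <- round(glen * cumsum(c(0.25, 0.15, 0.20, 0.15, 0.25)))
      bounds <- c(0L, as.integer(cuts))
      part_type <- c("exon", "intron", "exon", "intron", "exon")
      features[[length(features) + 1]] <- tibble(
        chrom = cn, type = "gene", start = s, end = s + glen - 1L,
        strand = strand, ID = gid, family_id = NA_character_,
        te_class = NA_character_, superfamily = NA_character_,
        Parent = NA_character_
      )
      for (k in seq_along(part_type)) {
        features[[length(features) + 1]] <- tibble(
          chrom = cn, type = part_type[k],
          start = s + bounds[k], end = s + bounds[k + 1] - 1L,
          strand = strand, ID = paste0(gid, "_", part_type[k], k),
          family_id = NA_character_, te_class = NA_character_,
          superfamily = NA_character_, Parent = gid
        )
      }
    }
  }

  ## --- repeat families with RIP ----------------------------------------
  for (spec in cfg$families) {
    unit <- random_seq(spec$unit_length,
                       if (is.na(spec$unit_gc)) cfg$gc_background
                       else spec$unit_gc)
    d <- (1 - spec$target_identity) / 2  # per-copy divergence from ancestor
    copies <- vapply(seq_len(spec$n_copies), function(i) {
      b <- chars(unit)
      if (d > 0) {
        hit <- which(runif(length(b)) < d)
        for (p in hit) b[p] <- sample(setdiff(DNA_BASES, b[p]), 1)
      }
      paste(b, collapse = "")
    }, character(1))
    names(copies) <- paste0(spec$family_id, "_c", seq_len(spec$n_copies))
    fam_rate <- if (is.na(spec$rip_rate)) cfg$rip_rate else spec$rip_rate
    if (spec$rip && fam_rate > 0) {
      ripped <- apply_rip(copies, fam_rate, cfg$rip_context_weights)
    } else {
      ripped <- list(copies = copies,
                     sites = tibble(copy_id = character(), pos = integer(),
                                    context = character(), ref = character(),
                                    obs = character()))
    }
    n_minus <- round(spec$strand_mix * spec$n_copies)
    strands <- sample(c(rep("-", n_minus),
                        rep("+", spec$n_copies - n_minus)))
    expressed <- runif(spec$n_copies) < spec$expressed_frac
    clustered <- !is.na(spec$chrom)
    next_start <- if (clustered) as.integer(spec$start) else NA_integer_
    for (i in seq_len(spec$n_copies)) {
      cid <- names(ripped$copies)[i]
      cn <- if (clustered) spec$chrom else sample(chrom_names, 1)
      s <- place_interval(cfg$chrom_length, spec$unit_length, occupied[[cn]],
                          fixed_start = if (clustered) next_start
                                        else NA_integer_)
      e <- s + spec$unit_length - 1L
      if (clustered) next_start <- e + 151L
      occupied[[cn]] <- add_row(occupied[[cn]], start = s, end = e)
      placed <- if (strands[i] == "+") ripped$copies[[i]]
                else revcomp_chr(ripped$copies[[i]])
      chroms[[cn]][s:e] <- chars(placed)
      features[[length(features) + 1]] <- tibble(
        chrom = cn, type = "transposable_element", start = s, end = e,
        strand = strands[i], ID = cid, family_id = spec$family_id,
        te_class = spec$te_class, superfamily = spec$superfamily,
        Parent = NA_character_
      )
      te_truth[[length(te_truth) + 1]] <- tibble(
        te_id = cid, family_id = spec$family_id, chrom = cn, start = s,
        end = e, strand = strands[i], te_class = spec$te_class,
        superfamily = spec$superfamily, expressed = expressed[i],
        methylated_family = spec$methylated
      )
      cs <- ripped$sites[ripped$sites$copy_id == cid, ]
      if (nrow(cs) > 0) {
        rip_truth[[length(rip_truth) + 1]] <- tibble(
          chrom = cn,
          pos = if (strands[i] == "+") s + cs$pos - 1L else e - cs$pos + 1L,
          strand = strands[i], context = cs$context,
          family_id = spec$family_id, copy_id = cid, copy_pos = cs$pos
        )
      }
    }
  }

  ## --- small-RNA loci ---------------------------------------------------
  arm_len <- 60L
  loop_len <- 8L
  for (k in seq_along(cfg$smrna_loci)) {
    spec <- cfg$smrna_loci[[k]]
    lid <- paste0("locus_", spec$class, "_", k)
    cn <- if (!is.na(spec$chrom)) spec$chrom else sample(chrom_names, 1)
    if (spec$class == "milRNA") {
      if (spec$length > arm_len - 15L) {
        abort("milRNA locus_spec length must fit on a hairpin arm (<= 45 bp)")
      }
      hp_len <- 2L * arm_len + loop_len
      hp_start <- if (!is.na(spec$start)) as.integer(spec$start) - 10L
                  else place_interval(cfg$chrom_length, hp_len, occupied[[cn]])
      hairpin <- draw_hairpin(arm_len, loop_len, cfg$gc_background)
      if (spec$strand == "-") hairpin <- revcomp_chr(hairpin)
      hp_end <- hp_start + hp_len - 1L
      chroms[[cn]][hp_start:hp_end] <- chars(hairpin)
      occupied[[cn]] <- add_row(occupied[[cn]], start = hp_start, end = hp_end)
      ## the read-emitting window sits on the 5' arm (3' arm for minus)
      l_start <- if (spec$strand == "+") hp_start + 10L
                 else hp_end - 10L - spec$length + 1L
      l_end <- l_start + spec$length - 1L
      loci_truth[[length(loci_truth) + 1]] <- tibble(
        locus_id = lid, class = "milRNA", chrom = cn, start = l_start,
        end = l_end, strand = spec$strand, reads_fwd = spec$reads_plus,
        reads_rev = spec$reads_minus, read_len_min = spec$read_len_min,
        read_len_max = spec$read_len_max, hairpin_start = hp_start,
        hairpin_end = hp_end
      )
    } else {
      s <- place_interval(cfg$chrom_length, spec$length, occupied[[cn]],
                          fixed_start = spec$start)
      e <- s + spec$length - 1L
      occupied[[cn]] <- add_row(occupied[[cn]], start = s, end = e)
      loci_truth[[length(loci_truth) + 1]] <- tibble(
        locus_id = lid, class = "disiRNA", chrom = cn, start = s, end = e,
        strand = "+", reads_fwd = spec$reads_plus,
        reads_rev = spec$reads_minus, read_len_min = spec$read_len_min,
        read_len_max = spec$read_len_max, hairpin_start = NA_integer_,
        hairpin_end = NA_integer_
      )
    }
  }

  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = "")
  )
  names(genome) <- chrom_names
  empty_loci <- tibble(
    locus_id = character(), class = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    reads_fwd = integer(), reads_rev = integer(), read_len_min = integer(),
    read_len_max = integer(), hairpin_start = integer(),
    hairpin_end = integer()
  )
  truth <- list(
    rip_sites = if (length(rip_truth)) bind_rows(rip_truth) else
      tibble(chrom = character(), pos = integer(), strand = character(),
             context = character(), family_id = character(),
             copy_id = character(), copy_pos = integer()),
    te_copies = if (length(te_truth)) bind_rows(te_truth) else
      tibble(te_id = character(), family_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), te_class = character(),
             superfamily = character(), expressed = logical(),
             methylated_family = logical()),
    loci = if (length(loci_truth)) bind_rows(loci_truth) else empty_loci
  )
  truth$expressed_te <- truth$te_copies$te_id[truth$te_copies$expressed]
  structure(
    list(genome = genome,
         features = if (length(features)) bind_rows(features) else
           tibble(chrom = character(), type = character(), start = integer(),
                  end = integer(), strand = character(), ID = character(),
                  family_id = character(), te_class = character(),
                  superfamily = character(), Parent = character()),
         truth = truth, config = cfg),
    class = "defense_sim"
  )
}

## draw hairpin arms until the bundled folder scores the precursor <= -20
draw_hairpin <- function(arm_len, loop_len, gc, mismatch = 0.08,
                         mfe_max = -20) {
  for (try in 1:50) {
    arm <- random_seq(arm_len, gc)
    arm2 <- chars(revcomp_chr(arm))
    flip <- which(runif(arm_len) < mismatch)
    for (p in flip) arm2[p] <- sample(setdiff(DNA_BASES, arm2[p]), 1)
    hp <- paste0(arm, random_seq(loop_len, 0.2),
                 paste(arm2, collapse = ""))
    if (fold_rna(hp)$mfe <= mfe_max) return(hp)
  }
  abort("could not draw a hairpin reaching the MFE bound")
}

#' @export
print.defense_sim <- function(x, ...) {
  cat("<defense_sim> ", length(x$genome), " chromosome(s), ",
      sum(Biostrings::width(x$genome)), " bp\n", sep = "")
  cat("  planted: ", nrow(x$truth$te_copies), " TE copies, ",
      nrow(x$truth$rip_sites), " RIP sites, ",
      nrow(x$truth$loci), " smRNA loci\n", sep = "")
  invisible(x)
}
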