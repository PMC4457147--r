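## Simulation configuration.
##
## The defaults here ARE the study conditions the downstream analyses are
## exercised under: a GC-rich fungal genome (55%), repeat families >= 400 bp
## at >= 80% identity, CpG-preferring RIP, a methylome concentrated at CpG
## sites inside TEs (98.7% of methylated calls), and small-RNA loci that are
## either strand-biased hairpin (milRNA) or strand-balanced (disiRNA) pileups
## over a uniform background.  See the methods vignette for the rationale
## behind every number.

SUPERFAMILY_CLASS <- c(
  LINE = "I", LTR = "I", DIRS = "I", PLE = "I",
  TIR = "II", helitron = "II", MITE = "II"
)

#' Describe one repeat family to plant in the synthetic genome
#'
#' @param family_id identifier for the family.
#' @param unit_length length of the ancestral unit in bp (>= 400; mirrors the
#'   repeat inclusion rule used throughout the RIP analysis).
#' @param n_copies number of copies to plant (>= 2).
#' @param target_identity mean pairwise identity among copies before RIP
#'   (>= 0.80); 1 plants identical copies so that RIP is the only mutational
#'   process.
#' @param strand_mix fraction of copies planted on the minus strand.
#' @param superfamily TE superfamily label (`LINE`, `LTR`, `DIRS`, `PLE` are
#'   class I; `TIR`, `helitron`, `MITE` class II; `unclassified` needs
#'   `te_class`).
#' @param te_class `"I"` or `"II"`; derived from `superfamily` when possible.
#' @param rip whether this family is subjected to the RIP process.
#' @param rip_rate optional per-family RIP rate overriding the genome-wide
#'   `sim_config()$rip_rate` (RIP dosage differs between families in real
#'   genomes; a heavily-RIP'd cluster is what the defense-region scan
#'   looks for).
#' @param methylated whether copies of this family receive TE-level
#'   methylation (otherwise the genic background rate applies).
#' @param expressed_frac fraction of copies flagged transcriptionally active
#'   (ground truth for the expression stage).
#' @param unit_gc GC fraction of the ancestral unit (`NA` = the genome
#'   background).  Long-RIP'd repeat families are AT-rich in real genomes;
#'   setting this below the background plants the low-GC hallmark of a
#'   defense region.
#' @param chrom,start optional fixed placement: copies are laid down
#'   consecutively from `start` on `chrom` (used to plant clustered
#'   RIP/methylation regions); by default copies are scattered.
#' @return a `family_spec` list.
#' @export
family_spec <- function(family_id, unit_length = 1000, n_copies = 4,
                        target_identity = 0.92, strand_mix = 0.25,
                        superfamily = "LTR", te_class = NULL,
                        rip = TRUE, rip_rate = NA_real_, methylated = TRUE,
                        expressed_frac = 0.33, unit_gc = NA_real_,
                        chrom = NA_character_, start = NA_integer_) {
  if (unit_length < 400) {
    abort("family_spec: unit_length must be >= 400 bp")
  }
  if (n_copies < 2) abort("family_spec: n_copies must be >= 2")
  if (target_identity < 0.80 || target_identity > 1) {
    abort("family_spec: target_identity must be in [0.80, 1]")
  }
  if (strand_mix < 0 || strand_mix > 1) {
    abort("family_spec: strand_mix must be in [0, 1]")
  }
  if (is.null(te_class)) {
    te_class <- unname(SUPERFAMILY_CLASS[superfamily])
    if (is.na(te_class)) {
      abort("family_spec: te_class required for unclassified superfamily")
    }
  }
  structure(
    list(family_id = family_id, unit_length = as.integer(unit_length),
         n_copies = as.integer(n_copies), target_identity = target_identity,
         strand_mix = strand_mix, superfamily = superfamily,
         te_class = te_class, rip = isTRUE(rip), rip_rate = rip_rate,
         methylated = isTRUE(methylated), expressed_frac = expressed_frac,
         unit_gc = unit_gc, chrom = chrom, start = start),
    class = "family_spec"
  )
}

#' Describe one small-RNA locus to plant
#'
#' @param class `"milRNA"` (strand-biased reads over a planted hairpin) or
#'   `"disiRNA"` (balanced reads from both strands).
#' @param chrom chromosome name (`NA` = assign at generation time).
#' @param start 1-based start of the read-emitting interval (`NA` = place
#'   randomly).
#' @param length length of the read-emitting interval in bp.
#' @param reads_plus,reads_minus reads emitted from each strand (for minus-
#'   strand milRNA loci the labels follow the genome, so `reads_plus` is the
#'   count on the locus strand given by `strand`).
#' @param strand dominant strand of a milRNA locus.
#' @param read_len_min,read_len_max read-length range (within 18-30 nt).
#' @return a `locus_spec` list.
#' @export
locus_spec <- function(class = c("milRNA", "disiRNA"), chrom = NA_character_,
                       start = NA_integer_, length = NULL,
                       reads_plus = NULL, reads_minus = NULL, strand = "+",
                       read_len_min = 20, read_len_max = 24) {
  class <- match.arg(class)
  if (is.null(length)) length <- if (class == "milRNA") 40L else 400L
  if (is.null(reads_plus)) reads_plus <- if (class == "milRNA") 60L else 45L
  if (is.null(reads_minus)) reads_minus <- if (class == "milRNA") 1L else 40L
  if (read_len_min < 18 || read_len_max > 30 || read_len_min > read_len_max) {
    abort("locus_spec: read lengths must satisfy 18 <= min <= max <= 30")
  }
  structure(
    list(class = class, chrom = chrom, start = start,
         length = as.integer(length), reads_plus = as.integer(reads_plus),
         reads_minus = as.integer(reads_minus), strand = strand,
         read_len_min = as.integer(read_len_min),
         read_len_max = as.integer(read_len_max)),
    class = "locus_spec"
  )
}

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic-genome generator.  All rates are
#' probabilities in `[0, 1]`; weight maps need not be normalised (they are
#' rescaled internally).
#'
#' @param seed integer seed; the whole simulation is deterministic given the
#'   config (including this seed).
#' @param n_chrom,chrom_length number and length (bp) of chromosomes.
#' @param gc_background background GC fraction drawn i.i.d. per base.
#' @param families list of [family_spec()] entries.
#' @param rip_rate per-eligible-site C->T probability for the most-preferred
#'   context (other contexts are scaled by `rip_context_weights`).
#' @param rip_context_weights named weights over `CpA`, `CpC`, `CpG`, `CpT`.
#' @param meth_rate_te,meth_rate_genic fraction of cytosines methylated
#'   inside TE intervals and elsewhere.
#' @param meth_context_weights named weights over `CpG`, `CHG`, `CHH` for
#'   methylated sites.
#' @param smrna_loci list of [locus_spec()] entries.
#' @param background_read_rate uniform background small-RNA reads per kb.
#' @param n_genes genes planted per chromosome (each with exon/intron
#'   structure, so feature-level summaries have something to partition).
#' @param gene_length planted gene length in bp.
#' @param bs_coverage mean bisulfite read coverage (Poisson).
#' @param bs_meth_level per-read methylation probability at a methylated
#'   cytosine.
#' @param bs_error per-read failed-conversion probability at an
#'   unmethylated cytosine.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 100000L,
                       gc_background = 0.55,
                       families = list(family_spec("fam1")),
                       rip_rate = 0.10,
                       rip_context_weights = c(CpA = 0.25, CpC = 0.10,
                                               CpG = 0.55, CpT = 0.10),
                       meth_rate_te = 0.09, meth_rate_genic = 0.008,
                       meth_context_weights = c(CpG = 0.987, CHG = 0.008,
                                                CHH = 0.005),
                       smrna_loci = list(),
                       background_read_rate = 2,
                       n_genes = 5L, gene_length = 1500L,
                       bs_coverage = 30, bs_meth_level = 0.95,
                       bs_error = 0.005) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              gc_background = gc_background, families = families,
              rip_rate = rip_rate, rip_context_weights = rip_context_weights,
              meth_rate_te = meth_rate_te, meth_rate_genic = meth_rate_genic,
              meth_context_weights = meth_context_weights,
              smrna_loci = smrna_loci,
              background_read_rate = background_read_rate,
              n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length),
              bs_coverage = bs_coverage, bs_meth_level = bs_meth_level,
              bs_error = bs_error)
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  check_rate <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      abort(paste0("sim_config: '", field, "' must be in [0, 1]"))
    }
  }
  for (f in c("gc_background", "rip_rate", "meth_rate_te",
              "meth_rate_genic", "bs_meth_level", "bs_error")) {
    check_rate(f)
  }
  for (f in c("rip_context_weights", "meth_context_weights")) {
    w <- cfg[[f]]
    if (any(w < 0) || sum(w) <= 0) {
      abort(paste0("sim_config: '", f, "' must be nonnegative with sum > 0"))
    }
  }
  if (cfg$n_chrom < 1) abort("sim_config: 'n_chrom' must be >= 1")
  needed <- c(
    vapply(cfg$families, function(f) f$unit_length, numeric(1)),
    vapply(cfg$smrna_loci, function(l) l$length + 2L * 80L, numeric(1))
  )
  if (length(needed) > 0 && max(needed) > cfg$chrom_length) {
    abort("sim_config: 'chrom_length' is smaller than the largest planted feature")
  }
  cfg
}
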