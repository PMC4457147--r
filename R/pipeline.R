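## Run configuration and the end-to-end pipeline.

default_run_config <- function() {
  list(
    seed = 1L,
    simulate = NULL,   # sim_config() fields; NULL = run from input files
    inputs = NULL,     # list(genome=, features=, cx=, smrna=, rnaseq=)
    rip = list(window = 500L, step = 100L, min_length = 400L,
               min_identity = 0.80, model = "consensus"),
    methylome = list(min_cov = 4, min_frac = 0.5),
    smrna = list(min_density_mil = 270, min_density_disi = 60,
                 strand_fold = 10, mfe_max = -20, mfei_min = 0.8,
                 flank = 80, balance_max = 2, max_gap = 50, min_reads = 10,
                 multimap = "fractional", backend = "stack"),
    integrate = list(min_rip = 1, min_mc = 1, max_mismatches = 2,
                     max_hits = 1, min_reads = 1, min_windows = 5)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !k %in% c("families", "smrna_loci", "inputs")) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline run configuration
#'
#' YAML keys mirror the arguments of the stage functions; unspecified
#' values fall back to the package defaults (every default is visible in
#' the returned list).  `simulate:` holds [sim_config()] fields, with
#' `families:` and `smrna_loci:` as lists of [family_spec()] /
#' [locus_spec()] fields.
#'
#' @param path path to a YAML file, or a list already in config shape.
#' @return the merged configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg <- merge_config(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

build_sim_config <- function(cfg) {
  s <- cfg$simulate
  s$seed <- s$seed %||% cfg$seed
  s$families <- lapply(s$families %||% list(),
                       function(f) do.call(family_spec, f))
  s$smrna_loci <- lapply(s$smrna_loci %||% list(),
                         function(l) do.call(locus_spec, l))
  do.call(sim_config, s)
}

write_tsv_prov <- function(x, path, header) {
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Run the full genome-defense pipeline
#'
#' Stages run in dependency order: simulate (when a `simulate:` block is
#' configured) or load inputs, then RIP analysis, methylome scoring,
#' small-RNA locus calling, and integration.  Every output file starts
#' with a provenance comment (package version, config hash, seed), and a
#' run summary is written at the end.  Reruns with the same configuration
#' produce byte-identical outputs.
#'
#' @param config a YAML path or configuration list (see
#'   [read_run_config()]).
#' @param outdir output directory (created if needed); no stage writes
#'   outside it.
#' @return invisibly, a list with the main in-memory results
#'   (`sim`, `rip_sites`, `spectrum`, `tracks`, `calls`,
#'   `feature_methylation`, `loci`, `records`, `crosstab`, `regions`,
#'   `summary`).
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- read_run_config(config)
  if (is.null(cfg$simulate)) {
    need <- c("genome", "features", "cx", "smrna", "rnaseq")
    paths <- unlist(cfg$inputs[need])
    missing <- need[!need %in% names(cfg$inputs)]
    gone <- paths[!file.exists(paths)]
    if (length(missing) > 0 || length(gone) > 0) {
      abort(paste0("run_pipeline: missing input(s) before any stage ran: ",
                   paste(c(missing, gone), collapse = ", ")))
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenance_header(cfg, cfg$seed)
  out <- function(f) file.path(outdir, f)

  ## --- stage 1: obtain data --------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- generate_genome(build_sim_config(cfg))
    genome <- sim$genome
    features <- sim$features
    meth <- simulate_methylome(sim)
    calls <- meth$calls
    smrna_aln <- simulate_smrna(genome, sim$truth$loci,
                                sim$config$background_read_rate,
                                seed = sim$config$seed)
    rnaseq <- simulate_rnaseq(genome, sim$truth$te_copies,
                              seed = sim$config$seed)
    write_fasta(genome, out("genome.fa"))
    write_gff3(features, out("features.gff3"))
    write_cx(calls, out("calls.cx"), header = prov)
    write_bed6(smrna_aln[, c("chrom", "start", "end", "name", "score",
                             "strand")],
               out("smrna.bed"), header = prov)
    write_bed6(rnaseq, out("rnaseq.bed"), header = prov)
    write_tsv_prov(sim$truth$rip_sites, out("truth_rip_sites.tsv"), prov)
    write_tsv_prov(sim$truth$te_copies, out("truth_te_copies.tsv"), prov)
    write_tsv_prov(sim$truth$loci, out("truth_loci.tsv"), prov)
    write_tsv_prov(meth$truth, out("truth_methylation.tsv"), prov)
  } else {
    sim <- NULL
    genome <- read_fasta(cfg$inputs$genome)
    features <- read_gff3(cfg$inputs$features)
    calls <- read_cx(cfg$inputs$cx)
    smrna_aln <- read_bed6(cfg$inputs$smrna)
    rnaseq <- read_bed6(cfg$inputs$rnaseq, extended = TRUE)
  }
  calls <- add_binary_calls(calls, cfg$methylome$min_cov,
                            cfg$methylome$min_frac)

  ## --- stage 2: RIP -----------------------------------------------------
  fams <- extract_repeat_families(genome, features,
                                  min_length = cfg$rip$min_length,
                                  min_identity = cfg$rip$min_identity,
                                  model = cfg$rip$model)
  rip_sites <- if (length(fams) > 0) {
    bind_rows(lapply(fams, call_rip_sites))
  } else {
    call_rip_sites_empty()
  }
  spectrum <- mutation_spectrum(fams)
  preference <- dinucleotide_preference(rip_sites)
  tracks <- windowed_tracks(genome, rip_sites, calls,
                            window = cfg$rip$window, step = cfg$rip$step)
  if (nrow(rip_sites) > 0) {
    write_bed6(tibble(chrom = rip_sites$chrom, start = rip_sites$pos,
                      end = rip_sites$pos, name = rip_sites$copy_id,
                      score = 1, strand = rip_sites$strand,
                      context = rip_sites$context),
               out("rip_sites.bed"), header = prov)
  }
  write_tsv_prov(tidy(spectrum), out("rip_spectrum.tsv"), prov)
  write_tsv_prov(preference, out("rip_preference.tsv"), prov)
  write_tsv_prov(tracks, out("window_tracks.tsv"), prov)
  write_bedgraph(tracks, "gc_fraction", out("gc.bedGraph"), prov)
  write_bedgraph(tracks, "cri", out("cri.bedGraph"), prov)

  ## --- stage 3: methylome ----------------------------------------------
  feat_sub <- features[features$type %in%
                         c("transposable_element", "gene", "exon",
                           "intron"), , drop = FALSE]
  fm <- feature_methylation(feat_sub, calls)
  fm_sum <- feature_methylation_summary(fm)
  ctx <- context_composition(calls)
  rate <- genome_methylation_rate(calls)
  write_tsv_prov(fm, out("feature_methylation.tsv"), prov)
  write_tsv_prov(fm_sum, out("feature_methylation_summary.tsv"), prov)
  write_tsv_prov(ctx, out("context_composition.tsv"), prov)
  msites <- calls[calls$is_methylated, , drop = FALSE]
  if (nrow(msites) > 0) {
    write_bed6(tibble(chrom = msites$chrom, start = msites$pos,
                      end = msites$pos, name = msites$context,
                      score = msites$count_methylated,
                      strand = msites$strand),
               out("methylated_sites.bed"), header = prov)
  }

  ## --- stage 4: small-RNA loci -----------------------------------------
  sm <- cfg$smrna
  loci <- classify_loci(smrna_aln, genome,
                        min_density_mil = sm$min_density_mil,
                        min_density_disi = sm$min_density_disi,
                        strand_fold = sm$strand_fold, mfe_max = sm$mfe_max,
                        mfei_min = sm$mfei_min, flank = sm$flank,
                        balance_max = sm$balance_max, max_gap = sm$max_gap,
                        min_reads = sm$min_reads, multimap = sm$multimap,
                        backend = sm$backend)
  write_tsv_prov(loci, out("smrna_loci.tsv"), prov)
  mil <- loci[loci$class == "milRNA", , drop = FALSE]
  write_tsv_prov(
    mil[, c("chrom", "start", "end", "dominant_strand", "mature_seq",
            "mfe", "gc_percent", "mfei")],
    out("milrna_report.tsv"), prov
  )

  ## --- stage 5: integration --------------------------------------------
  te_feat <- features[features$type == "transposable_element", ,
                      drop = FALSE]
  ig <- cfg$integrate
  result <- list(sim = sim, rip_sites = rip_sites, spectrum = spectrum,
                 preference = preference, tracks = tracks, calls = calls,
                 feature_methylation = fm, loci = loci)
  if (nrow(te_feat) > 0) {
    expr <- flag_te_expression(te_feat, rnaseq,
                               max_mismatches = ig$max_mismatches,
                               max_hits = ig$max_hits,
                               min_reads = ig$min_reads)
    records <- te_activity_records(te_feat, expr, rip_sites, calls,
                                   min_rip = ig$min_rip, min_mc = ig$min_mc)
    ct <- crosstab(records)
    sf <- silencing_fraction(records)
    regions <- detect_defense_regions(tracks,
                                      min_windows = ig$min_windows)
    write_tsv_prov(records, out("te_status.tsv"), prov)
    write_tsv_prov(tidy(ct), out("te_crosstab.tsv"), prov)
    write_tsv_prov(regions, out("defense_regions.tsv"), prov)
    result$records <- records
    result$crosstab <- ct
    result$silencing_fraction <- sf
    result$regions <- regions
  }

  ## --- summary ----------------------------------------------------------
  summary <- list(
    n_chromosomes = length(genome),
    genome_bp = sum(Biostrings::width(genome)),
    n_repeat_families = length(fams),
    n_rip_sites = nrow(rip_sites),
    fraction_CG_to_TA = unname(spectrum$fraction_CG_to_TA),
    methylation_rate = unname(rate),
    n_methylated_sites = sum(calls$is_methylated),
    n_loci = nrow(loci),
    n_milrna = sum(loci$class == "milRNA"),
    n_disirna = sum(loci$class == "disiRNA"),
    n_te = nrow(te_feat),
    silencing_fraction_classI_rip_mc =
      if (!is.null(result$silencing_fraction)) {
        unname(result$silencing_fraction)
      } else NA,
    n_defense_regions = if (!is.null(result$regions)) {
      nrow(result$regions)
    } else 0L
  )
  writeLines(c(prov, yaml::as.yaml(summary)), out("summary.yaml"))
  result$summary <- summary
  invisible(result)
}

call_rip_sites_empty <- function() {
  tibble(family_id = character(), copy_id = character(), column = integer(),
         copy_pos = integer(), chrom = character(), pos = integer(),
         strand = character(), context = character(), ref = character(),
         obs = character())
}

## bedGraph: 0-based half-open, one value column
write_bedgraph <- function(tracks, metric, path, header = NULL) {
  x <- tibble(chrom = tracks$chrom, start = tracks$start - 1L,
              end = tracks$end, value = tracks[[metric]])
  lines <- c(header,
             paste0("track type=bedGraph name=", metric))
  writeLines(lines, path)
  readr::write_tsv(x, path, col_names = FALSE, append = TRUE,
                   progress = FALSE)
  invisible(path)
}
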