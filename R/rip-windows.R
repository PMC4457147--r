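## RIP indices and sliding-window tracks.

RIP_DINUCS <- c("TA", "AT", "CA", "TG", "AC", "GT")

#' RIP indices of a sequence window
#'
#' Product index `TpA / ApT`, substrate index
#' `(CpA + TpG) / (ApC + GpT)` and the composite RIP index
#' `CRI = product - substrate`, computed from overlapping dinucleotide
#' counts on the given strand.  RIP depletes its CpA/TpG substrate and
#' deposits TpA product, so positive CRI marks RIP-affected sequence.  An
#' index with a zero denominator is undefined (`NA`) -- no pseudocounts are
#' added -- and the CRI is defined only when both components are.
#'
#' @param window a single sequence (character or [Biostrings::DNAString]),
#'   length >= 2.
#' @return one-row tibble: the six dinucleotide counts (`tpa`, `apt`,
#'   `cpa`, `tpg`, `apc`, `gpt`), `product_index`, `substrate_index`,
#'   `cri`.
#' @export
#' @examples
#' rip_indices("TACATGAT")
rip_indices <- function(window) {
  if (!inherits(window, "DNAString")) {
    window <- Biostrings::DNAString(as.character(window))
  }
  if (length(window) < 2) abort("rip_indices: window length must be >= 2")
  freq <- Biostrings::dinucleotideFrequency(window)
  k <- as.numeric(freq[RIP_DINUCS])
  names(k) <- RIP_DINUCS
  product <- if (k[["AT"]] > 0) k[["TA"]] / k[["AT"]] else NA_real_
  substrate <- if (k[["AC"]] + k[["GT"]] > 0) {
    (k[["CA"]] + k[["TG"]]) / (k[["AC"]] + k[["GT"]])
  } else NA_real_
  tibble(
    tpa = k[["TA"]], apt = k[["AT"]], cpa = k[["CA"]], tpg = k[["TG"]],
    apc = k[["AC"]], gpt = k[["GT"]],
    product_index = product, substrate_index = substrate,
    cri = if (is.na(product) || is.na(substrate)) NA_real_
          else product - substrate
  )
}

#' Sliding-window genome tracks: GC, RIP indices, site densities
#'
#' Tiles each chromosome with windows of `window` bp advancing by `step`
#' bp (the classic 500/100 moving-window scan) and computes per window the
#' GC fraction, the RIP product/substrate/composite indices, the number of
#' called RIP sites and the number of methylated cytosines.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param rip_sites optional tibble with `chrom`, `pos` (e.g. from
#'   [call_rip_sites()]).
#' @param methyl_calls optional tibble with `chrom`, `pos` and, if present,
#'   a logical `is_methylated` used to keep methylated calls only.
#' @param window,step window and step sizes in bp (`window >= step >= 1`).
#' @param include_tail also emit a final truncated window covering the
#'   chromosome tail when the tiling does not reach the end.
#' @return tibble: `chrom`, `start`, `end` (1-based inclusive),
#'   `gc_fraction`, `product_index`, `substrate_index`, `cri`,
#'   `rip_site_count`, `mc_count`.
#' @export
windowed_tracks <- function(genome, rip_sites = NULL, methyl_calls = NULL,
                            window = 500L, step = 100L,
                            include_tail = FALSE) {
  if (step < 1 || window < step) {
    abort("windowed_tracks: need window >= step >= 1")
  }
  if (!is.null(methyl_calls) && "is_methylated" %in% names(methyl_calls)) {
    methyl_calls <- methyl_calls[methyl_calls$is_methylated, , drop = FALSE]
  }
  out <- list()
  for (cn in names(genome)) {
    L <- Biostrings::width(genome)[[match(cn, names(genome))]]
    if (window > L) {
      warn(paste0("windowed_tracks: window larger than ", cn, "; skipped"))
      next
    }
    v <- chrom_chars(genome, cn)
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    if (include_tail && max(ends) < L) {
      starts <- c(starts, max(starts) + step)
      ends <- c(ends, L)
    }
    cum_gc <- cumsum(v %in% c("G", "C"))
    di <- paste0(v[-L], v[1 + seq_len(L - 1)])
    cum_di <- lapply(setNames(RIP_DINUCS, RIP_DINUCS),
                     function(d) cumsum(di == d))
    wsum <- function(cs, s, e) cs[e] - c(0, cs)[s]  # c(0,cs)[s] = cs[s-1]
    gc <- wsum(cum_gc, starts, ends) / (ends - starts + 1L)
    k <- lapply(cum_di, function(cs) wsum(cs, starts, pmax(ends - 1L, starts)))
    product <- ifelse(k$AT > 0, k$TA / k$AT, NA_real_)
    substrate <- ifelse(k$AC + k$GT > 0,
                        (k$CA + k$TG) / (k$AC + k$GT), NA_real_)
    count_in <- function(events) {
      if (is.null(events)) return(rep(0L, length(starts)))
      p <- sort(events$pos[events$chrom == cn])
      if (length(p) == 0) return(rep(0L, length(starts)))
      findInterval(ends, p) - findInterval(starts - 1L, p)
    }
    out[[length(out) + 1]] <- tibble(
      chrom = cn, start = starts, end = ends, gc_fraction = gc,
      product_index = product, substrate_index = substrate,
      cri = ifelse(is.na(product) | is.na(substrate), NA_real_,
                   product - substrate),
      rip_site_count = count_in(rip_sites),
      mc_count = count_in(methyl_calls)
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gc_fraction = numeric(), product_index = numeric(),
                  substrate_index = numeric(), cri = numeric(),
                  rip_site_count = integer(), mc_count = integer()))
  }
  bind_rows(out)
}
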