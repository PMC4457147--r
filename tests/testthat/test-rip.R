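fam_from_seqs <- function(seqs, ...) {
  repeat_family(tibble::tibble(copy_id = names(seqs), seq = unname(seqs)),
                ...)
}

test_that("consensus is the per-column majority with GC-ward ties", {
  expect_equal(build_consensus(c("C", "C", "T")), "C")     # majority
  expect_equal(build_consensus(c("C", "T")), "C")          # tie -> C
  expect_equal(build_consensus(c("G", "A")), "G")          # tie -> G
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACGT")), "ACGT")
  expect_equal(build_consensus(c("A-", "A-", "AC")), "A-") # gap majority
  expect_equal(build_consensus(c("A-", "AC")), "AC")       # gap tie -> base
  expect_error(build_consensus("ACGT"), "at least 2")
})

test_that("highest-gc model picks the GC-richest copy as pre-RIP state", {
  expect_equal(build_consensus(c("ATAT", "GCGC", "ATGC"),
                               model = "highest-gc"), "GCGC")
})

test_that("C->T against the consensus is called with its CpN context", {
  fam <- fam_from_seqs(c(a = "ACGA", b = "ACGA", c = "ATGA"))
  sites <- call_rip_sites(fam)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$copy_id, "c")
  expect_equal(sites$column, 2L)
  expect_equal(sites$context, "CpG")
  expect_equal(sites$strand, "+")
})

test_that("G->A is reported as a minus-strand C->T with minus context", {
  fam <- fam_from_seqs(c(a = "TCGT", b = "TCGT", c = "TCAT"))
  sites <- call_rip_sites(fam)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$column, 3L)
  expect_equal(sites$strand, "-")
  expect_equal(sites$context, "CpG")   # minus-strand reading ACGA -> ATGA
})

test_that("identical copies yield no sites; each mutated copy counts", {
  expect_equal(nrow(call_rip_sites(fam_from_seqs(c(a = "ACGT",
                                                   b = "ACGT")))), 0)
  fam <- fam_from_seqs(c(a = "ACGA", b = "ACGA", c = "ACGA", d = "ACGA",
                         e = "ATGA", f = "ATGA", g = "ATGA"))
  expect_equal(nrow(call_rip_sites(fam)), 3)   # one event per copy
})

test_that("genome coordinates and strands map through the copy interval", {
  copies <- tibble::tibble(
    copy_id = c("p", "m", "q"),
    chrom = "chr1", start = c(101L, 501L, 901L),
    end = c(104L, 504L, 904L), strand = c("+", "-", "+"),
    seq = c("ACGA", "ACGA", "ATGA")
  )
  sites <- call_rip_sites(repeat_family(copies))
  expect_equal(sites$copy_id, "q")
  expect_equal(sites$pos, 901L + 2L - 1L)      # column 2, plus strand
  m <- repeat_family(dplyr::mutate(copies,
                                   seq = c("ACGA", "ATGA", "ACGA")))
  s2 <- call_rip_sites(m)
  expect_equal(s2$copy_id, "m")
  expect_equal(s2$pos, 504L - 2L + 1L)         # column 2 from the 3' end
  expect_equal(s2$strand, "-")
})

test_that("mutation spectrum counts every substitution class per event", {
  fam <- fam_from_seqs(c(a = "CCCA", b = "CCCA", c = "TTTG"))
  ## 3 C->T plus 1 A->G from copy c
  sp <- mutation_spectrum(fam)
  expect_equal(sp$total, 4)
  expect_equal(sp$fraction_CG_to_TA, 0.75)
  expect_equal(sp$counts$n[sp$counts$class == "AT>GC"], 1L)
  expect_equal(sum(sp$counts$n), sp$total)
  expect_equal(sum(sp$counts$fraction), 1)
})

test_that("empty spectrum leaves fractions undefined", {
  sp <- mutation_spectrum(fam_from_seqs(c(a = "ACGT", b = "ACGT")))
  expect_equal(sp$total, 0)
  expect_true(is.na(sp$fraction_CG_to_TA))
  expect_equal(glance(sp)$total, 0)
})

test_that("dinucleotide preference preserves counts and normalises", {
  sites <- tibble::tibble(context = c("CpA", "CpA", "CpG", "CpG"))
  pref <- dinucleotide_preference(sites)
  expect_equal(sort(pref$fraction), c(0.5, 0.5))
  expect_equal(sum(pref$n), 4L)
  expect_equal(nrow(dinucleotide_preference(sites[0, , drop = FALSE])), 0)
  one <- dinucleotide_preference(tibble::tibble(context = rep("CpG", 5)))
  expect_equal(one$fraction, 1)
})

test_that("planted context weights are recovered within 3 sigma", {
  w <- c(CpA = 0.3, CpC = 0.05, CpG = 0.6, CpT = 0.05)
  out <- make_rip_family(77, n_copies = 4, len = 4000, rate = 0.3,
                         weights = w)
  fam <- fam_from_seqs(out$copies)
  sites <- call_rip_sites(fam)
  pref <- dinucleotide_preference(sites)
  ## expected context mix from the ancestor's context counts x weights
  anc <- strsplit(out$ancestor, "")[[1]]
  ctx_of <- c(A = "CpA", C = "CpC", G = "CpG", T = "CpT")
  elig <- which(anc == "C" & seq_along(anc) < length(anc))
  ctx_n <- table(ctx_of[anc[elig + 1]])
  wn <- w / max(w)
  exp_w <- ctx_n[names(wn)] * wn
  exp_p <- as.numeric(exp_w / sum(exp_w))
  names(exp_p) <- names(wn)
  n <- sum(pref$n)
  for (cx in pref$context) {
    p <- exp_p[[cx]]
    sigma <- sqrt(p * (1 - p) / n)
    obs <- pref$fraction[pref$context == cx]
    expect_lt(abs(obs - p), 3 * sigma + 1e-9)
  }
})

test_that("center-star alignment handles an internal deletion", {
  seqs <- c(long = "ACGTACGTACGT", short = "ACGTCGTACGT")  # one A deleted
  aligned <- align_family(seqs)
  expect_equal(nchar(aligned[["long"]]), nchar(aligned[["short"]]))
  expect_equal(gsub("-", "", aligned[["short"]]), seqs[["short"]])
  expect_equal(sum(strsplit(aligned[["short"]], "")[[1]] == "-"), 1)
})

test_that("family extraction enforces the length and identity rules", {
  cfg <- sim_config(seed = 13, n_chrom = 1, chrom_length = 30000,
                    families = list(family_spec("keep", 600, 3, 1.0),
                                    family_spec("drop", 450, 2, 0.80)),
                    rip_rate = 0)
  sim <- generate_genome(cfg)
  ## make the second family diverge far below the identity floor
  fams <- extract_repeat_families(sim$genome, sim$features,
                                  min_identity = 0.99)
  expect_true("keep" %in% names(fams))
  expect_false("drop" %in% names(fams))
  short <- extract_repeat_families(sim$genome, sim$features,
                                   min_length = 700)
  expect_equal(length(short), 0)
})
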