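# Shared fixtures and independent oracles used across the suite.

random_dna <- function(n, seed = NULL, gc = 0.5) {
  gen <- function() {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Exact local alignment score oracle via Biostrings (independent of the
# package's C++ implementation); searches both strands.
biostrings_local_score <- function(frag, target, match = 1, mismatch = -2,
                                   gap_open = 5, gap_ext = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  s1 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
  s2 <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag),
    Biostrings::reverseComplement(Biostrings::DNAString(target)),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
  max(s1, s2)
}

# Minimum parsimony steps of a two-site character pair over all unrooted
# topologies (phangorn enumeration + Fitch), minus each site's own minimum:
# the brute-force refined-incompatibility oracle for small taxon sets.
brute_force_extra_steps <- function(site_i, site_j) {
  ok <- site_i > 0 & site_j > 0
  a <- site_i[ok]; b <- site_j[ok]
  n <- length(a)
  if (n < 4) return(0L)
  labs <- paste0("t", seq_len(n))
  dat <- matrix(c(c("a", "c", "g", "t")[a], c("a", "c", "g", "t")[b]),
                ncol = 2, dimnames = list(labs, NULL))
  pd <- phangorn::phyDat(dat, type = "DNA")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  best <- min(vapply(trees, function(tr) phangorn::fitch(tr, pd), numeric(1)))
  as.integer(best - (length(unique(a)) - 1) - (length(unique(b)) - 1))
}

# build an ani_matrix object from plain symmetric ANI values (coverage 1)
toy_ani_matrix <- function(sym, coverage = NULL) {
  ids <- rownames(sym)
  cov <- coverage
  if (is.null(cov)) {
    cov <- matrix(1, nrow(sym), ncol(sym), dimnames = dimnames(sym))
  }
  structure(list(ids = ids, ani = sym, coverage = cov, sym_ani = sym,
                 params = anib_params()), class = "ani_matrix")
}

# small clonal population sample used by several recombination tests
clonal_sample <- function(n_taxa, length_bp, divergence, seed,
                          recomb_rate = 0, tract_mean = 300) {
  cfg <- sim_config(genome_length = length_bp, n_genes = 0, seed = seed,
                    groups = list(group_design("A", n_taxa,
                                               within_divergence = divergence,
                                               stem_divergence = 0,
                                               recomb_rate = recomb_rate,
                                               tract_mean_len = tract_mean)))
  simulate_sample(cfg)
}
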