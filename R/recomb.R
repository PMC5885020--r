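#' Parsimony-informative sites of an alignment
#'
#' Columns with at least two states each carried by at least two taxa; gaps
#' and N are missing and ignored per column.
#'
#' @param seqs named character vector of aligned sequences
#' @return list with `positions` (1-based column indices) and `states`
#'   (sites x taxa integer matrix, 1..4, 0 missing)
#' @export
informative_sites <- function(seqs) {
  m <- aln_int(seqs)
  counts <- apply(m, 2, function(col) {
    tb <- tabulate(col[col > 0], 4)
    sum(tb >= 2)
  })
  pos <- which(counts >= 2)
  list(positions = pos, states = t(m[, pos, drop = FALSE]))
}

#' Refined incompatibility of two aligned sites
#'
#' The minimum number of extra mutations, beyond each character's parsimony
#' lower bound, needed to fit both sites on a single tree: the cyclomatic
#' number E - V + C of their partition-intersection graph (vertices: observed
#' states of each site; edges: observed joint state pairs), computed over taxa
#' observed at both sites.
#'
#' @param site_i,site_j integer vectors of states (1..4, 0 missing) or
#'   character vectors of bases
#' @return non-negative integer
#' @export
refined_incompatibility <- function(site_i, site_j) {
  conv <- function(x) {
    if (is.character(x)) {
      v <- match(toupper(x), DNA_BASES)
      v[is.na(v)] <- 0L
      v
    } else as.integer(x)
  }
  st <- rbind(conv(site_i), conv(site_j))
  pair_score_cpp(st)
}

#' Pairwise homoplasy index (PHI) test for intragene recombination
#'
#' The statistic is the mean refined incompatibility over all unordered pairs
#' of informative sites at most `w` alignment positions apart. The null
#' permutes the positions of the informative sites with their state vectors
#' fixed; recombination makes incompatibility grow with distance, so a low
#' observed near-pair mean is the signal and
#' p = (1 + #\{phi_perm <= phi_obs\}) / (n_perm + 1).
#'
#' With fewer than two informative sites (or no near pair) the gene is
#' reported untestable rather than erroring: the test is conservative at low
#' diversity.
#'
#' @param seqs named character vector of aligned sequences (>= 4 taxa)
#' @param w window in alignment positions
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return object of class `phi_result`: phi, p_value, n_informative,
#'   n_pairs, untestable flag
#' @export
phi_test <- function(seqs, w = 100L, n_perm = 1000L, seed = 1L) {
  if (length(seqs) < 4) stop_phagani("PHI needs >= 4 taxa")
  info <- informative_sites(seqs)
  s <- length(info$positions)
  res <- structure(list(gene = NULL, n_informative = s, w = w,
                        phi = NA_real_, p_value = NA_real_,
                        n_perm = n_perm, seed = seed, n_pairs = 0L,
                        untestable = TRUE), class = "phi_result")
  if (s < 2) return(res)
  scores <- incompat_matrix_cpp(info$states)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(s), integer(s)))
  })
  st <- phi_stats_cpp(scores, info$positions, as.integer(w), perms)
  if (st$n_pairs == 0) return(res)
  res$phi <- st$phi
  res$n_pairs <- st$n_pairs
  res$p_value <- (1 + sum(st$perm <= st$phi)) / (n_perm + 1)
  res$untestable <- FALSE
  res
}

#' Run the PHI test over a set of gene alignments
#'
#' @param gene_alns named list of alignments (named character vectors)
#' @param w,n_perm,seed as [phi_test()]
#' @return data.frame: gene, n_informative, phi, p_value, untestable
#' @export
phi_scan <- function(gene_alns, w = 100L, n_perm = 1000L, seed = 1L) {
  rows <- lapply(seq_along(gene_alns), function(i) {
    r <- phi_test(gene_alns[[i]], w = w, n_perm = n_perm,
                  seed = seed + i - 1L)
    data.frame(gene = names(gene_alns)[i], n_informative = r$n_informative,
               phi = r$phi, p_value = r$p_value, untestable = r$untestable)
  })
  do.call(rbind, rows)
}

# columns on which a branch can register a change: observed on both sides
branch_effective_length <- function(obs, in_clade) {
  sum(colSums(obs[in_clade, , drop = FALSE]) > 0 &
      colSums(obs[!in_clade, , drop = FALSE]) > 0)
}

#' SNP-density scan for recombinant tracts on a core alignment
#'
#' Iterates: (1) NJ tree on TN93 distances, (2) Fitch assignment of variant
#' columns to branches, (3) per branch, candidate windows are maximal runs of
#' at least `run_min_snps` branch SNPs with inter-SNP gaps of at most
#' `run_gap` columns; a run of k SNPs spanning l columns is called
#' recombinant when n_snps * P(Binom(l, background) >= k - 1) is below
#' alpha / n_branches_scanned: a scan-style Bonferroni over the possible
#' run-start SNPs (conditioning on the anchoring SNP) and over the branches
#' scanned. Detected tracts (trimmed to their outermost SNPs) are
#' masked in the descendant taxa and the scan repeats until stable or
#' `max_iter`.
#'
#' @param seqs named character vector: concatenated single-copy-core alignment
#' @param max_iter maximum scan iterations
#' @param alpha familywise significance level per branch
#' @param run_min_snps minimum SNPs seeding a candidate window
#' @param run_gap maximum gap (columns) between SNPs of one run
#' @param min_scan_len minimum alignment length
#' @return object of class `tract_scan`: `tracts` (branch, start, end
#'   0-based half-open, snps, p_value), final `tree`, `aln_length`,
#'   `branch_label`s of the final tree
#' @export
detect_recombinant_tracts <- function(seqs, max_iter = 5L, alpha = 0.05,
                                      run_min_snps = 3L, run_gap = 100L,
                                      min_scan_len = 1000L) {
  if (length(seqs) < 4) stop_phagani("need >= 4 taxa")
  L <- nchar(seqs[[1]])
  if (L < min_scan_len) stop_phagani("alignment shorter than min_scan_len")
  work <- seqs
  tracts <- list()
  fa <- NULL
  for (iter in seq_len(max_iter)) {
    dm <- tn93_distance(work)
    tree <- nj_tree(dm)
    fa <- fitch_assign(tree, work)
    obs <- aln_int(work)[fa$tree$tip.label, , drop = FALSE] > 0
    new_tract <- FALSE
    snps_per_edge <- table(fa$changes$edge)
    n_branches_tested <- sum(snps_per_edge >= run_min_snps)
    alpha_fw <- alpha / max(1, n_branches_tested)
    for (e in unique(fa$changes$edge)) {
      cols <- sort(fa$changes$column[fa$changes$edge == e])
      child <- fa$tree$edge[e, 2]
      clade <- strsplit(fa$branch_label[e], ",")[[1]]
      in_clade <- rownames(obs) %in% clade
      eff_len <- branch_effective_length(obs, in_clade)
      if (eff_len <= 0 || length(cols) < run_min_snps) next
      dens <- length(cols) / eff_len
      runs <- split(cols, cumsum(c(1, diff(cols) > run_gap)))
      for (r in runs) {
        k <- length(r)
        if (k < run_min_snps) next
        span <- r[k] - r[1] + 1
        p <- length(cols) * pbinom(k - 2, span, dens, lower.tail = FALSE)
        if (p < alpha_fw) {
          tracts[[length(tracts) + 1]] <-
            data.frame(branch = fa$branch_label[e], start = r[1] - 1L,
                       end = r[k], snps = k, p_value = p, iter = iter)
          # mask for the descendant taxa
          gapfill <- strrep("-", r[k] - r[1] + 1)
          for (tx in clade)
            substr(work[[tx]], r[1], r[k]) <- gapfill
          new_tract <- TRUE
        }
      }
    }
    if (!new_tract) break
  }
  tracts <- if (length(tracts) > 0) do.call(rbind, tracts) else
    data.frame(branch = character(0), start = integer(0), end = integer(0),
               snps = integer(0), p_value = numeric(0), iter = integer(0))
  structure(list(tracts = tracts, tree = fa$tree,
                 branch_label = fa$branch_label, aln_length = L),
            class = "tract_scan")
}

#' Per-branch clonal-frame fractions
#'
#' The clonal frame of a branch is the portion of the alignment not covered
#' by recombinant tracts on that branch: 1 - (recombinant columns / alignment
#' columns). Branches without tracts score 1. Reported with the min-max range
#' over all branches.
#'
#' @param scan a `tract_scan` (or a tract data.frame plus `aln_length` and
#'   `branch_label`)
#' @return object of class `clonal_frame`: per-branch data.frame and `range`
#' @export
clonal_frame <- function(scan) {
  labels <- scan$branch_label
  frac <- setNames(rep(1, length(labels)), labels)
  tr <- scan$tracts
  if (nrow(tr) > 0) {
    for (b in unique(tr$branch)) {
      sub <- tr[tr$branch == b, , drop = FALSE]
      cols <- unique(unlist(mapply(function(s, e) seq(s + 1, e),
                                   sub$start, sub$end, SIMPLIFY = FALSE)))
      f <- 1 - length(cols) / scan$aln_length
      if (b %in% names(frac)) frac[b] <- f else frac <- c(frac, setNames(f, b))
    }
  }
  structure(list(branches = data.frame(branch = names(frac),
                                       clonal_fraction = unname(frac)),
                 range = range(frac)), class = "clonal_frame")
}
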