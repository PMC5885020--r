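#' Spearman Mantel test between two distance matrices
#'
#' Spearman correlation of the unfolded upper triangles, with a one-tailed
#' (positive association) permutation p-value obtained by permuting the taxa
#' labels of the second matrix. Rank vectors are precomputed and only
#' re-indexed per permutation, so large permutation counts stay cheap.
#'
#' @param m1,m2 symmetric distance matrices over the same taxa
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list with `r` (Spearman statistic) and `p_value`
#' @export
mantel_spearman <- function(m1, m2, n_perm = 199L, seed = 1L) {
  n <- nrow(m1)
  stopifnot(all(dim(m1) == dim(m2)), n >= 3)
  ut <- which(upper.tri(m1), arr.ind = TRUE)
  x <- rank(m1[upper.tri(m1)])
  y <- rank(m2[upper.tri(m2)])
  pair_idx <- matrix(0L, n, n)
  pair_idx[ut] <- seq_len(nrow(ut))
  pair_idx <- pair_idx + t(pair_idx)
  r_obs <- suppressWarnings(cor(x, y))
  if (is.na(r_obs)) return(list(r = NA_real_, p_value = NA_real_))
  count <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      sig <- sample.int(n)
      map <- pair_idx[cbind(sig[ut[, 1]], sig[ut[, 2]])]
      if (suppressWarnings(cor(x, y[map])) >= r_obs) cnt <- cnt + 1L
    }
    cnt
  })
  list(r = r_obs, p_value = (1 + count) / (n_perm + 1))
}

#' Per-gene TN93 distance matrices over a shared taxon set
#'
#' Restricts every gene alignment to the shared taxa (the intersection of all
#' alignments' taxa unless given) and computes TN93 distances; genes with a
#' saturated (infinite) pair are dropped with a warning.
#'
#' @param gene_alns named list of alignments (named character vectors)
#' @param taxa shared taxon ids (default: intersection over genes)
#' @return object of class `distance_matrix_set`: `matrices` (named list),
#'   `taxa`, `dropped`
#' @export
gene_distance_set <- function(gene_alns, taxa = NULL) {
  if (length(gene_alns) == 0) stop_phagani("no gene alignments")
  taxa <- taxa %||% Reduce(intersect, lapply(gene_alns, names))
  taxa <- sort(taxa)
  if (length(taxa) < 2) stop_phagani("fewer than 2 shared taxa")
  mats <- list()
  dropped <- character(0)
  for (g in names(gene_alns)) {
    aln <- gene_alns[[g]]
    if (!all(taxa %in% names(aln))) { dropped <- c(dropped, g); next }
    d <- tn93_distance(aln[taxa])
    if (any(!is.finite(d))) {
      warning("gene ", g, " has saturated pairs; dropped")
      dropped <- c(dropped, g)
      next
    }
    mats[[g]] <- d
  }
  if (length(mats) == 0) stop_phagani("no usable genes")
  structure(list(matrices = mats, taxa = taxa, dropped = dropped),
            class = "distance_matrix_set")
}

#' Congruence among distance matrices (CADM) with a-posteriori Mantel tests
#'
#' Kendall's coefficient of concordance W over the rank-transformed unfolded
#' distance matrices (ties mid-ranked, standard tie correction), with a
#' permutation null that permutes each matrix's taxa independently; W = 1
#' means all gene distance matrices agree, W = 0 the opposite. The global
#' test is ape's CADM implementation. The a-posteriori battery computes the
#' Spearman correlation of every matrix pair's unfolded distances with a
#' one-tailed Mantel permutation p-value.
#'
#' @param dms a `distance_matrix_set` (or plain named list of matrices)
#' @param n_perm permutations for the global test
#' @param n_perm_mantel permutations per Mantel test (0 skips the battery)
#' @param seed integer seed
#' @return object of class `cadm_result`: W, chi2, p_value, r_bar (mean
#'   pairwise Spearman), `mantel` data.frame, n_genes, n_taxa
#' @export
cadm <- function(dms, n_perm = 999L, n_perm_mantel = 199L, seed = 1L) {
  mats <- if (inherits(dms, "distance_matrix_set")) dms$matrices else dms
  p <- length(mats)
  if (p < 2) stop_phagani("need >= 2 matrices")
  n <- nrow(mats[[1]])
  if (n < 4) stop_phagani("need >= 4 taxa")
  big <- do.call(rbind, mats)
  glob <- with_seed(seed, ape::CADM.global(big, p, n, nperm = n_perm,
                                           silent = TRUE))
  ca <- glob$congruence_analysis
  W <- ca["W", 1]; chi2 <- ca["Chi2", 1]; pval <- ca["Prob.perm", 1]
  # pairwise Spearman of unfolded upper triangles + Mantel p-values
  ut <- upper.tri(mats[[1]])
  unfolded <- vapply(mats, function(m) m[ut], numeric(sum(ut)))
  combs <- combn(p, 2)
  r <- numeric(ncol(combs)); mp <- rep(NA_real_, ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    r[k] <- suppressWarnings(cor(unfolded[, i], unfolded[, j], method = "spearman"))
    if (n_perm_mantel > 0) {
      mt <- mantel_spearman(mats[[i]], mats[[j]], n_perm = n_perm_mantel,
                            seed = seed + k)
      mp[k] <- mt$p_value
    }
  }
  mantel <- data.frame(gene_i = names(mats)[combs[1, ]],
                       gene_j = names(mats)[combs[2, ]],
                       r = r, p_value = mp)
  structure(list(W = unname(W), chi2 = unname(chi2), p_value = unname(pval),
                 r_bar = mean(r), mantel = mantel, n_genes = p, n_taxa = n,
                 n_perm = n_perm, seed = seed),
            class = "cadm_result")
}

#' Progressive congruence over nested samples
#'
#' Starting from a base sample and an ordered list of additions, each step
#' re-derives the shared single-copy gene families over the current sample,
#' rebuilds the TN93 matrices and runs CADM with the Mantel battery: the
#' congruence trajectory as progressively more divergent phages (satellites,
#' then a whole related group) are included.
#'
#' @param genomes named character vector of all genome sequences
#' @param gene_table gene table over all genomes
#' @param base character vector of genome ids of the starting group
#' @param additions ordered list of character vectors added step by step
#' @param n_perm,n_perm_mantel,seed see [cadm()]
#' @param alpha significance level for the Mantel significant fraction
#' @return object of class `progressive_result`: `steps` data.frame (step,
#'   n_taxa, n_genes, W, p_value, r_bar, mantel_sig_fraction), `details` list
#'   of `cadm_result`s
#' @export
progressive_cadm <- function(genomes, gene_table, base, additions = list(),
                             n_perm = 999L, n_perm_mantel = 199L, seed = 1L,
                             alpha = 0.05) {
  genes_all <- extract_genes(genomes, gene_table)
  samples <- list(base)
  acc <- base
  for (add in additions) {
    acc <- c(acc, add)
    samples <- append(samples, list(acc))
  }
  rows <- list(); details <- list()
  for (s in seq_along(samples)) {
    ids <- samples[[s]]
    label <- if (s == 1) "base" else paste0("step", s - 1)
    if (length(ids) < 4) {
      rows[[s]] <- data.frame(step = label, n_taxa = length(ids),
                              n_genes = NA, W = NA, p_value = NA,
                              r_bar = NA, mantel_sig_fraction = NA,
                              flagged = "fewer than 4 genomes")
      next
    }
    sub <- genes_all[genes_all$genome_id %in% ids, , drop = FALSE]
    fams <- cluster_families(sub)
    scc <- core_genome(fams)$single_copy_core
    if (length(scc) < 2) {
      rows[[s]] <- data.frame(step = label, n_taxa = length(ids),
                              n_genes = length(scc), W = NA, p_value = NA,
                              r_bar = NA, mantel_sig_fraction = NA,
                              flagged = "fewer than 2 shared genes")
      next
    }
    alns <- family_alignments(sub, fams, scc)
    dms <- gene_distance_set(alns, taxa = ids)
    res <- cadm(dms, n_perm = n_perm, n_perm_mantel = n_perm_mantel,
                seed = seed + s)
    details[[label]] <- res
    rows[[s]] <- data.frame(step = label, n_taxa = length(ids),
                            n_genes = res$n_genes, W = res$W,
                            p_value = res$p_value, r_bar = res$r_bar,
                            mantel_sig_fraction =
                              mean(res$mantel$p_value < alpha, na.rm = TRUE),
                            flagged = "")
  }
  structure(list(steps = do.call(rbind, rows), details = details),
            class = "progressive_result")
}

#' Frequency-weighted consensus splits from gene trees
#'
#' Pools the nontrivial splits of all input trees; each split's weight is the
#' fraction of trees containing it (each tree contributes a split at most
#' once). Splits below `min_freq` are discarded. The consensus-network
#' substrate: conflicting splits depict incongruence among gene trees.
#'
#' @param trees list of `phylo` trees over identical taxa
#' @param min_freq minimum occurrence frequency to retain a split
#' @return object of class `split_set`: data.frame `splits` (split, weight,
#'   size), `n_trees`, `taxa`
#' @export
consensus_splits <- function(trees, min_freq = 0.1) {
  if (length(trees) < 2) stop_phagani("need >= 2 trees")
  taxa <- sort(trees[[1]]$tip.label)
  for (tr in trees) if (!setequal(tr$tip.label, taxa))
    stop_phagani("trees must share an identical taxon set")
  pooled <- unlist(lapply(trees, function(tr) unique(tree_splits(tr)$split)))
  tb <- table(pooled) / length(trees)
  keep <- tb[tb >= min_freq]
  splits <- data.frame(split = names(keep), weight = as.numeric(keep))
  splits <- splits[order(-splits$weight, splits$split), , drop = FALSE]
  rownames(splits) <- NULL
  splits$size <- vapply(strsplit(splits$split, "\\|"), length, integer(1))
  structure(list(splits = splits, n_trees = length(trees), taxa = taxa),
            class = "split_set")
}

#' Write a split set as a NEXUS splits block
#'
#' SplitsTree-compatible: a TAXA block and an ST_SPLITS block listing each
#' split's weight and the taxon indices of its canonical side.
#'
#' @param ss a `split_set`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_splits_nexus <- function(ss, path) {
  taxa <- ss$taxa
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(sprintf("BEGIN Taxa;\nDIMENSIONS ntax=%d;\nTAXLABELS", length(taxa)), con)
  writeLines(sprintf("[%d] '%s'", seq_along(taxa), taxa), con)
  writeLines(";\nEND;", con)
  writeLines(sprintf("BEGIN st_splits;\nDIMENSIONS ntax=%d nsplits=%d;",
                     length(taxa), nrow(ss$splits)), con)
  writeLines("FORMAT labels=no weights=yes;\nMATRIX", con)
  for (i in seq_len(nrow(ss$splits))) {
    side <- strsplit(ss$splits$split[i], "\\|")[[1]]
    idx <- sort(match(side, taxa))
    writeLines(sprintf("%g\t%s,", ss$splits$weight[i],
                       paste(idx, collapse = " ")), con)
  }
  writeLines(";\nEND;", con)
  invisible(path)
}
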