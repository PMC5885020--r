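random_dm <- function(n, seed) {
  m <- withr::with_seed(seed, matrix(runif(n * n), n))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  m
}

test_that("Mantel statistic matches vegan and p-values agree", {
  base <- random_dm(10, 1)
  noisy <- base + random_dm(10, 2) * 0.15
  mine <- mantel_spearman(base, noisy, n_perm = 499, seed = 3)
  ref <- withr::with_seed(4,
    vegan::mantel(stats::as.dist(base), stats::as.dist(noisy),
                  method = "spearman", permutations = 499))
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(mine$p_value, 0.01)
  expect_lt(ref$signif, 0.01)
  # unrelated matrices: both tests non-significant
  far <- random_dm(10, 9)
  mine2 <- mantel_spearman(base, far, n_perm = 499, seed = 5)
  expect_gt(mine2$p_value, 0.05)
})

test_that("CADM closed forms: perfect agreement and perfect discordance", {
  m <- random_dm(8, 11)
  r <- cadm(list(g1 = m, g2 = m, g3 = m), n_perm = 99, n_perm_mantel = 0,
            seed = 1)
  expect_equal(r$W, 1)
  expect_equal(r$p_value, 1 / 100)
  expect_equal(r$r_bar, 1)
  rev <- max(m) + min(m[upper.tri(m)]) - m
  diag(rev) <- 0
  r2 <- cadm(list(a = m, b = rev), n_perm = 99, n_perm_mantel = 0, seed = 1)
  expect_equal(r2$W, 0)
  expect_equal(r2$r_bar, -1)
})

test_that("mean Spearman and W satisfy the concordance identity", {
  mats <- lapply(1:5, function(i) random_dm(9, 20 + i))
  names(mats) <- paste0("g", 1:5)
  r <- cadm(mats, n_perm = 49, n_perm_mantel = 0, seed = 2)
  p <- length(mats)
  expect_equal(r$r_bar, (p * r$W - 1) / (p - 1), tolerance = 1e-9)
  # brute-force W from direct rank arithmetic (no ties with runif draws)
  ut <- upper.tri(mats[[1]])
  ranks <- vapply(mats, function(m) rank(m[ut]), numeric(sum(ut)))
  S <- sum((rowSums(ranks) - mean(rowSums(ranks)))^2)
  m_ <- sum(ut)
  W_direct <- 12 * S / (p^2 * (m_^3 - m_))
  expect_equal(r$W, W_direct, tolerance = 1e-9)
})

test_that("W is invariant under simultaneous taxa relabeling", {
  mats <- lapply(1:3, function(i) random_dm(8, 30 + i))
  names(mats) <- paste0("g", 1:3)
  ord <- withr::with_seed(5, sample(8))
  perm <- lapply(mats, function(m) m[ord, ord])
  r1 <- cadm(mats, n_perm = 49, n_perm_mantel = 0, seed = 3)
  r2 <- cadm(perm, n_perm = 49, n_perm_mantel = 0, seed = 3)
  expect_equal(r1$W, r2$W, tolerance = 1e-12)
})

test_that("congruent gene sets score high W, independent ones low", {
  tr <- withr::with_seed(41, ape::rtree(12, rooted = FALSE))
  D <- ape::cophenetic.phylo(tr)
  congruent <- withr::with_seed(42, lapply(1:10, function(i) {
    n <- matrix(runif(144, 0, 0.08 * mean(D)), 12)
    m <- D + (n + t(n)) / 2
    diag(m) <- 0
    m
  }))
  names(congruent) <- paste0("g", 1:10)
  r <- cadm(congruent, n_perm = 99, n_perm_mantel = 0, seed = 6)
  expect_gt(r$W, 0.6)
  expect_lte(r$p_value, 0.01)
  independent <- withr::with_seed(43, lapply(1:10, function(i)
    ape::cophenetic.phylo(ape::rtree(12, rooted = FALSE))))
  names(independent) <- paste0("g", 1:10)
  # align taxa order across matrices
  taxa <- rownames(independent[[1]])
  independent <- lapply(independent, function(m) m[taxa, taxa])
  r2 <- cadm(independent, n_perm = 99, n_perm_mantel = 0, seed = 7)
  expect_lt(r2$W, 0.2)
})

test_that("gene distance sets drop saturated genes and need shared taxa", {
  s <- clonal_sample(5, 3000, 0.05, seed = 61)
  alns <- list(g1 = s$genomes, g2 = s$genomes)
  # saturate one gene
  sat <- s$genomes
  sat[[1]] <- paste(rep("A", 3000), collapse = "")
  sat[[2]] <- paste(rep("G", 3000), collapse = "")
  alns$bad <- sat
  expect_warning(dms <- gene_distance_set(alns), "saturated")
  expect_setequal(names(dms$matrices), c("g1", "g2"))
  expect_equal(dms$dropped, "bad")
  expect_error(gene_distance_set(list()), "no gene alignments")
})

test_that("consensus splits weight bipartitions by occurrence", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  ss <- consensus_splits(list(t1, t1, t1))
  expect_true(all(ss$splits$weight == 1))
  expect_equal(nrow(ss$splits), nrow(tree_splits(t1)))
  # one NNI: the conflicting splits halve, the shared split stays at 1
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1,E:1);")
  ss2 <- consensus_splits(list(t1, t2), min_freq = 0.1)
  w <- setNames(ss2$splits$weight, ss2$splits$split)
  expect_equal(unname(w["A|B"]), 0.5)
  expect_equal(unname(w["A|C"]), 0.5)
  t3 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1,D:1);")
  ss3 <- consensus_splits(list(t1, t3), min_freq = 0.1)
  w3 <- setNames(ss3$splits$weight, ss3$splits$split)
  expect_equal(unname(w3["A|B"]), 1)   # cherry AB common to both trees
  bad <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,F:1);")
  expect_error(consensus_splits(list(t1, bad)), "identical taxon set")
})

test_that("NEXUS splits export lists every retained split", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  ss <- consensus_splits(list(t1, t1))
  path <- tempfile(fileext = ".nex")
  write_splits_nexus(ss, path)
  txt <- readLines(path)
  expect_true(any(grepl("^#NEXUS", txt)))
  expect_equal(sum(grepl("^[0-9]", txt)), nrow(ss$splits))
  unlink(path)
})

test_that("progressive congruence with no additions equals plain CADM", {
  cfg <- sim_config(genome_length = 6000, n_genes = 8,
                    gene_length_range = c(300, 700), seed = 71,
                    groups = list(group_design("A", 5, 0.05, 0,
                                               recomb_rate = 3,
                                               tract_mean_len = 800)))
  s <- simulate_sample(cfg)
  prog <- progressive_cadm(s$genomes, s$genes, names(s$genomes), list(),
                           n_perm = 99, n_perm_mantel = 0, seed = 4)
  expect_equal(nrow(prog$steps), 1)
  genes <- extract_genes(s$genomes, s$genes)
  fams <- cluster_families(genes)
  alns <- family_alignments(genes, fams)
  dms <- gene_distance_set(alns, taxa = names(s$genomes))
  direct <- cadm(dms, n_perm = 99, n_perm_mantel = 0, seed = 4 + 1)
  expect_equal(prog$steps$W, direct$W, tolerance = 1e-12)
})
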