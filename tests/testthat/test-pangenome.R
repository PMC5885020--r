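make_sample <- function(seed = 5, n_members = 4, n_genes = 8, loss = 0) {
  cfg <- sim_config(genome_length = 8000, n_genes = n_genes,
                    gene_length_range = c(300, 900), seed = seed,
                    groups = list(group_design("A", n_members, 0.03, 0,
                                               n_gene_loss = loss)))
  simulate_sample(cfg)
}

test_that("protein match statistics behave on constructed pairs", {
  s <- make_sample()
  g <- extract_genes(s$genomes, s$genes)
  a <- g$aa[1]
  pm <- protein_match(a, a)
  expect_equal(pm$aai, 100)
  expect_equal(pm$coverage_a, 1)
  expect_equal(pm$coverage_b, 1)
  half <- substr(a, 1, floor(nchar(a) / 2))
  pm2 <- protein_match(a, half)
  expect_equal(pm2$coverage_b, 1)
  expect_equal(pm2$coverage_a, nchar(half) / nchar(a), tolerance = 0.02)
  expect_equal(pm2$aai, 100)
})

test_that("protein identity equals a direct count on the alignment", {
  s <- make_sample()
  g <- extract_genes(s$genomes, s$genes)
  a <- g$aa[1]
  b <- g$aa[g$gene_id == g$gene_id[1]][2]   # ortholog from another genome
  pm <- protein_match(a, b)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b), type = "local",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  expect_equal(pm$aai, 100 * sum(ap == as_) / length(ap))
})

test_that("ortholog clustering recovers the simulated families", {
  s <- make_sample(seed = 7)
  g <- extract_genes(s$genomes, s$genes)
  fams <- cluster_families(g)
  expect_equal(length(fams$families), 8)
  core <- core_genome(fams)
  expect_equal(length(core$core), 8)
  expect_equal(length(core$single_copy_core), 8)
  # partition property: every gene in exactly one family
  all_members <- do.call(rbind, fams$families)
  expect_equal(nrow(all_members), nrow(g))
  expect_false(anyDuplicated(paste(all_members$genome_id,
                                   all_members$gene_id)) > 0)
})

test_that("clustering is invariant under genome input order", {
  s <- make_sample(seed = 9)
  g <- extract_genes(s$genomes, s$genes)
  f1 <- cluster_families(g)
  g2 <- g[rev(seq_len(nrow(g))), ]
  f2 <- cluster_families(g2)
  sig <- function(f) sort(vapply(f$families, function(m)
    paste(sort(paste(m$genome_id, m$gene_id)), collapse = ";"), character(1)))
  expect_identical(sig(f1), sig(f2))
})

test_that("unrelated random proteins stay singletons", {
  aa <- withr::with_seed(11, replicate(12, paste(
    sample(Biostrings::AA_STANDARD, 150, replace = TRUE), collapse = "")))
  g <- data.frame(genome_id = rep(c("x", "y"), each = 6),
                  gene_id = paste0("p", 1:12), start = 0, end = 450,
                  strand = "+", nt = NA, aa = aa)
  fams <- cluster_families(g)
  expect_equal(length(fams$families), 12)
  expect_true(all(vapply(fams$families, nrow, integer(1)) == 1))
})

test_that("a family missing from one genome leaves the core", {
  s <- make_sample(seed = 13)
  g <- extract_genes(s$genomes, s$genes)
  # drop 3 distinct genes from one genome
  victim <- unique(g$genome_id)[1]
  drop_genes <- unique(g$gene_id)[1:3]
  g2 <- g[!(g$genome_id == victim & g$gene_id %in% drop_genes), ]
  fams <- cluster_families(g2)
  core <- core_genome(fams)
  expect_equal(length(core$core), 8 - 3)
})

test_that("presence-absence dendrogram separates gene-content groups", {
  cfg <- sim_config(genome_length = 9000, n_genes = 10,
                    gene_length_range = c(300, 600), seed = 17,
                    groups = list(group_design("A", 4, 0.02, 0.08),
                                  group_design("B", 4, 0.02, 0.08,
                                               n_gene_loss = 3)))
  s <- simulate_sample(cfg)
  g <- extract_genes(s$genomes, s$genes)
  fams <- cluster_families(g)
  tr <- presence_absence_dendrogram(fams)
  a_ids <- grep("^A_", fams$genomes, value = TRUE)
  sp <- tree_splits(tr)
  sides <- strsplit(sp$split, "\\|")
  hit <- any(vapply(sides, function(sd)
    setequal(sd, a_ids) || setequal(sd, setdiff(fams$genomes, a_ids)),
    logical(1)))
  expect_true(hit)
  # identical content -> zero distance cherry is representable
  expect_error(presence_absence_dendrogram(
    cluster_families(g[g$genome_id %in% a_ids[1:2], ])), ">= 3")
})

test_that("group content differencing returns exactly the deleted families", {
  cfg <- sim_config(genome_length = 9000, n_genes = 10,
                    gene_length_range = c(300, 600), seed = 19,
                    groups = list(group_design("A", 4, 0.02, 0.08),
                                  group_design("B", 3, 0.02, 0.08,
                                               n_gene_loss = 3)))
  s <- simulate_sample(cfg)
  g <- extract_genes(s$genomes, s$genes)
  fams <- cluster_families(g)
  a_ids <- grep("^A_", fams$genomes, value = TRUE)
  b_ids <- grep("^B_", fams$genomes, value = TRUE)
  diff_ab <- group_content_diff(fams, a_ids, b_ids)
  lost <- s$truth$gene_loss$gene_id
  # families containing the lost ancestral genes, and only those
  fam_of <- function(gid) names(which(vapply(fams$families, function(m)
    gid %in% m$gene_id, logical(1))))
  expect_setequal(diff_ab, unlist(lapply(lost, fam_of)))
  expect_length(group_content_diff(fams, a_ids, setdiff(fams$genomes, a_ids)),
                length(lost))
  expect_error(group_content_diff(fams, a_ids, a_ids), "disjoint")
  expect_length(group_content_diff(fams, b_ids, a_ids), 0)
})
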