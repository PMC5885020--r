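test_that("informative sites are two-state-twice columns, missing ignored", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  expect_length(informative_sites(aln)$positions, 0)
  aln <- c(a = "AC", b = "AG", c = "GC", d = "GT")
  info <- informative_sites(aln)
  expect_equal(info$positions, 1L)       # A,A,G,G informative; ACGT singletons
  aln <- c(a = "A-", b = "AN", c = "GA", d = "GA")
  expect_equal(informative_sites(aln)$positions, 1L)
})

test_that("refined incompatibility scores the canonical small cases", {
  expect_equal(refined_incompatibility(c("A", "A", "G", "G"),
                                       c("C", "C", "T", "T")), 0)
  expect_equal(refined_incompatibility(c("A", "A", "G", "G"),
                                       c("C", "T", "C", "T")), 1)
  s <- c("A", "G", "A", "G", "T")
  expect_equal(refined_incompatibility(s, s), 0)
})

test_that("refined incompatibility equals the exhaustive parsimony oracle", {
  cases <- withr::with_seed(77, {
    lapply(1:120, function(i) {
      n <- sample(4:6, 1)
      list(i = sample(c(0:4), n, replace = TRUE, prob = c(1, 4, 4, 3, 3)),
           j = sample(c(0:4), n, replace = TRUE, prob = c(1, 4, 4, 3, 3)))
    })
  })
  for (cs in cases) {
    ok <- cs$i > 0 & cs$j > 0
    if (sum(ok) < 4) next
    mine <- refined_incompatibility(cs$i, cs$j)
    expect_equal(mine, brute_force_extra_steps(cs$i, cs$j))
  }
})

test_that("PHI is untestable below two informative sites and ties give p 1", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")
  r <- phi_test(aln, n_perm = 99)
  expect_true(r$untestable)
  expect_true(is.na(r$p_value))
  # two informative sites: the single pair is permutation invariant
  aln2 <- c(a = "AATT", b = "AATT", c = "GGTT", d = "GGAA")
  r2 <- phi_test(aln2, w = 100, n_perm = 99)
  expect_false(r2$untestable)
  expect_equal(r2$p_value, 1)
  expect_error(phi_test(aln2[1:3]), ">= 4 taxa")
})

test_that("PHI p-values are uniform under a diverse clonal null", {
  # diversity high enough that homoplasy is dense and ties in the statistic
  # are rare; at low diversity the permutation p is conservative by design
  pvals <- vapply(1:500, function(i) {
    s <- clonal_sample(15, 1500, divergence = 0.10, seed = 40000 + i)
    phi_test(s$genomes, w = 100, n_perm = 399, seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals[!is.na(pvals)], "punif"))
  expect_gt(ks$p.value, 0.01)
  # and conservative, not anticonservative, at low diversity
  p_low <- vapply(1:100, function(i) {
    s <- clonal_sample(12, 800, divergence = 0.05, seed = 60000 + i)
    phi_test(s$genomes, w = 100, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  expect_lte(mean(p_low < 0.05, na.rm = TRUE), 0.07)
})

test_that("PHI detects dense intragene recombination", {
  pvals <- vapply(1:40, function(i) {
    s <- clonal_sample(15, 1000, divergence = 0.05, seed = 50000 + i,
                       recomb_rate = 8, tract_mean = 300)
    phi_test(s$genomes, w = 100, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.8)
})

test_that("tract scan rejects degenerate input", {
  s <- clonal_sample(4, 500, 0.02, seed = 1)
  expect_error(detect_recombinant_tracts(s$genomes), "min_scan_len")
  expect_error(detect_recombinant_tracts(s$genomes[1:3]), ">= 4 taxa")
})

test_that("an implanted divergent tract is recovered on its branch only", {
  s <- clonal_sample(10, 30000, divergence = 0.01, seed = 3001)
  g1 <- s$genomes[[1]]
  seg <- withr::with_seed(100, mutate_fraction(substr(g1, 10001, 12000), 0.10))
  s$genomes[[1]] <- paste0(substr(g1, 1, 10000), seg, substr(g1, 12001, 30000))
  scan <- detect_recombinant_tracts(s$genomes)
  rec <- names(s$genomes)[1]
  tr <- scan$tracts[scan$tracts$branch == rec, , drop = FALSE]
  expect_gte(nrow(tr), 1)
  main <- tr[which.max(tr$snps), ]
  ov <- min(main$end, 12000) - max(main$start, 10000)
  expect_gte(ov / 2000, 0.9)
  expect_gte(ov / (main$end - main$start), 0.9)
  # masking is branch-local: other terminal branches stay clonal
  cf <- clonal_frame(scan)
  others <- setdiff(names(s$genomes), unique(scan$tracts$branch))
  fr <- cf$branches$clonal_fraction[cf$branches$branch %in% others]
  expect_true(all(fr == 1))
})

test_that("clonal frame fractions follow the tract arithmetic", {
  empty <- structure(list(tracts = data.frame(branch = character(0),
                                              start = integer(0),
                                              end = integer(0)),
                          branch_label = c("x", "y", "z"),
                          aln_length = 60000), class = "tract_scan")
  cf <- clonal_frame(empty)
  expect_true(all(cf$branches$clonal_fraction == 1))
  expect_equal(cf$range, c(1, 1))
  one <- empty
  one$tracts <- data.frame(branch = "x", start = 1000L, end = 4000L)
  cf1 <- clonal_frame(one)
  expect_equal(cf1$branches$clonal_fraction[cf1$branches$branch == "x"], 0.95)
  expect_equal(cf1$range, c(0.95, 1))
})

test_that("clonal frame shrinks as recombination intensifies", {
  rates <- c(0, 2, 6, 12)
  mins <- vapply(rates, function(rt) {
    mean(vapply(1:3, function(r) {
      s <- clonal_sample(8, 20000, divergence = 0.04, seed = 7000 + 10 * rt + r,
                         recomb_rate = rt, tract_mean = 2000)
      min(clonal_frame(detect_recombinant_tracts(s$genomes))$range)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mins) <= 0))
  expect_lt(mins[4], mins[1])
})
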