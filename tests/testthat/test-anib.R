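test_that("genome fragmentation follows the tiling and trailing rules", {
  f <- fragment_genome(random_dna(1000, seed = 1))
  expect_equal(nrow(f), 2)
  expect_equal(f$start, c(0, 500))
  expect_equal(f$end, c(500, 1000))
  f <- fragment_genome(random_dna(1250, seed = 1))
  expect_equal(nrow(f), 3)
  expect_equal(f$end[3], 1250)   # trailing 250 >= 250 kept
  f <- fragment_genome(random_dna(1100, seed = 1))
  expect_equal(nrow(f), 2)       # trailing 100 discarded
  expect_error(fragment_genome(""), "non-empty")
})

test_that("best_local_match finds exact substrings on either strand", {
  target <- random_dna(4000, seed = 2)
  frag <- substring(target, 1001, 1500)
  h <- best_local_match(frag, target)
  expect_equal(h$identity, 100)
  expect_equal(h$aligned_fraction, 1.0)
  hr <- best_local_match(frag, phagani:::revcomp_chr(target))
  expect_equal(hr$identity, 100)
  expect_equal(hr$aligned_fraction, 1.0)
  expect_equal(hr$score, h$score)
})

test_that("scattered mismatches give the directly counted identity", {
  target <- random_dna(3000, seed = 3)
  frag <- substring(target, 501, 1000)
  v <- strsplit(frag, "")[[1]]
  pos <- withr::with_seed(4, sort(sample(30:470, 25)))  # keep ends clean
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  h <- best_local_match(paste(v, collapse = ""), target)
  expect_equal(h$identity, 95.0)
  expect_equal(h$aligned_fraction, 1.0)
})

test_that("seeded-route scores match exact Smith-Waterman on small targets", {
  # same instance through both routes: seeded (forced) vs exact DP
  p <- anib_params()
  for (seed in 1:10) {
    target <- random_dna(3000, seed = 100 + seed)
    frag <- withr::with_seed(seed,
      mutate_fraction(substring(target, 701, 1200), 0.05))
    exact <- phagani:::align_fragments_cpp(frag, target, p$k, p$match,
                                           p$mismatch, p$gap_open, p$gap_ext,
                                           exact = TRUE)
    seeded <- phagani:::align_fragments_cpp(frag, target, p$k, p$match,
                                            p$mismatch, p$gap_open, p$gap_ext,
                                            exact = FALSE)
    expect_equal(seeded$score, exact$score)
  }
})

test_that("compute_anib recovers identity and coverage on known pairs", {
  g <- random_dna(50000, seed = 10)
  r <- compute_anib(substring(g, 1, 10000), substring(g, 1, 10000))
  expect_equal(r$ani, 100)
  expect_equal(r$coverage, 1)
  g2 <- withr::with_seed(11, mutate_fraction(g, 0.05))
  r <- compute_anib(g, g2)
  expect_lt(abs(r$ani - 95), 0.3)
  expect_gte(r$coverage, 0.99)
  r <- compute_anib(random_dna(50000, seed = 1), random_dna(50000, seed = 2))
  expect_lt(r$coverage, 0.02)
  expect_true(is.na(r$ani) || r$n_qualifying > 0)
})

test_that("ANI is monotone in divergence", {
  anis <- vapply(seq(0.01, 0.10, by = 0.01), function(d) {
    mean(vapply(1:5, function(r) {
      g <- random_dna(20000, seed = 300 + r)
      g2 <- withr::with_seed(round(1000 * d) * 50 + r, mutate_fraction(g, d))
      compute_anib(g, g2)$ani
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(anis) < 0))
})

test_that("all-versus-all matrices have the stated shape and symmetry", {
  g <- random_dna(3000, seed = 21)
  genomes <- c(a = g, b = g, c = g)
  am <- compute_all_anib(genomes)
  off <- am$ani[upper.tri(am$ani) | lower.tri(am$ani)]
  expect_true(all(off == 100))
  expect_equal(sum(!is.na(am$ani)) , 9)  # n(n-1) directional + diagonal
  expect_equal(am$sym_ani, t(am$sym_ani))
  expect_true(all(diag(am$sym_ani) == 100))
  expect_error(compute_all_anib(setNames(c(g, g), c("a", "a"))), "unique")
  expect_error(compute_all_anib(setNames(g, "a")), ">= 2")
})

test_that("group delineation is threshold clustering with connected components", {
  ids <- c("A", "B", "C", "D")
  m <- matrix(70, 4, 4, dimnames = list(ids, ids)); diag(m) <- 100
  m["A", "B"] <- m["B", "A"] <- 95
  m["C", "D"] <- m["D", "C"] <- 96
  m["A", "C"] <- m["C", "A"] <- 75
  part <- delineate_groups(toy_ani_matrix(m))
  expect_equal(unname(part$groups), list(c("A", "B"), c("C", "D")))
  # chaining: A-B 93, B-C 93, A-C 90 -> one group
  m2 <- matrix(70, 3, 3, dimnames = list(ids[1:3], ids[1:3])); diag(m2) <- 100
  m2["A", "B"] <- m2["B", "A"] <- 93
  m2["B", "C"] <- m2["C", "B"] <- 93
  m2["A", "C"] <- m2["C", "A"] <- 90
  part2 <- delineate_groups(toy_ani_matrix(m2))
  expect_equal(unname(part2$groups), list(c("A", "B", "C")))
  # all below cutoff -> all singletons
  m3 <- matrix(80, 3, 3, dimnames = list(ids[1:3], ids[1:3])); diag(m3) <- 100
  part3 <- delineate_groups(toy_ani_matrix(m3))
  expect_equal(length(part3$groups), 0)
  expect_setequal(part3$singletons, ids[1:3])
})

test_that("low-coverage edges cannot fuse groups", {
  ids <- c("A", "B", "C")
  m <- matrix(70, 3, 3, dimnames = list(ids, ids)); diag(m) <- 100
  m["A", "B"] <- m["B", "A"] <- 95   # genuine group
  m["B", "C"] <- m["C", "B"] <- 96   # high ANI but transfer-like
  cov <- matrix(1, 3, 3, dimnames = list(ids, ids))
  cov["B", "C"] <- cov["C", "B"] <- 0.15
  part <- delineate_groups(toy_ani_matrix(m, cov))
  expect_equal(unname(part$groups), list(c("A", "B")))
  expect_equal(part$singletons, "C")
})

test_that("satellite relations live in the stated ANI band, per group", {
  ids <- c("A", "B", "C", "D", "E")
  m <- matrix(60, 5, 5, dimnames = list(ids, ids)); diag(m) <- 100
  m["A", "B"] <- m["B", "A"] <- 95
  m["C", "D"] <- m["D", "C"] <- 96
  m["E", "A"] <- m["A", "E"] <- 88
  m["E", "C"] <- m["C", "E"] <- 87
  part <- delineate_groups(toy_ani_matrix(m))
  sats <- find_satellites(toy_ani_matrix(m), part)
  expect_equal(nrow(sats), 2)  # satellite of both groups
  expect_setequal(sats$genome, c("E", "E"))
  expect_equal(sort(sats$max_ani), c(87, 88))
})

test_that("transfer candidates are high-ANI low-coverage ordered pairs", {
  ids <- c("A", "B", "C")
  ani <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids)); diag(ani) <- 100
  cov <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids)); diag(cov) <- 1
  ani["A", "B"] <- ani["B", "A"] <- 95; cov["A", "B"] <- cov["B", "A"] <- 0.98
  ani["A", "C"] <- 96; cov["A", "C"] <- 0.15   # transfer-like
  ani["C", "A"] <- 95; cov["C", "A"] <- 0.18
  am <- structure(list(ids = ids, ani = ani, coverage = cov,
                       sym_ani = (ani + t(ani)) / 2, params = anib_params()),
                  class = "ani_matrix")
  fl <- flag_transfer_candidates(am)
  expect_equal(nrow(fl), 2)
  expect_setequal(paste(fl$query, fl$target), c("A C", "C A"))
})

test_that("a simulated long intergroup transfer is flagged from the truth log", {
  # donor group beyond the alignability limit: only the transferred ~10 kb
  # tract aligns, leaving the high-ANI / low-coverage signature
  cfg <- sim_config(genome_length = 50000, n_genes = 0, seed = 55,
                    groups = list(
                      group_design("A", 3, within_divergence = 0.02,
                                   stem_divergence = 0,
                                   intergroup_transfer_rate = 1,
                                   intergroup_donor = "C",
                                   intergroup_tract_mean = 10000),
                      group_design("C", 2, within_divergence = 0.02,
                                   stem_divergence = 0.55)))
  s <- simulate_sample(cfg)
  ev <- s$truth$events[s$truth$events$type == "intergroup", ]
  expect_gt(nrow(ev), 0)
  am <- compute_all_anib(s$genomes)
  fl <- flag_transfer_candidates(am)
  hit <- paste(ev$donor, ev$recipient)
  expect_true(any(paste(fl$query, fl$target) %in% hit))
  row <- fl[paste(fl$query, fl$target) %in% hit, ][1, ]
  expect_gte(row$ani, 95)
  expect_lte(row$coverage, 0.2)
  # same-group pairs share their whole genomes and are never flagged
  a_ids <- grep("^A_", names(s$genomes), value = TRUE)
  expect_false(any(fl$query %in% a_ids & fl$target %in% a_ids))
})

test_that("ANI report tables cover all defined pairs with default bins", {
  g <- random_dna(4000, seed = 30)
  genomes <- c(a = g,
               b = withr::with_seed(31, mutate_fraction(g, 0.03)),
               c = withr::with_seed(32, mutate_fraction(g, 0.05)))
  am <- compute_all_anib(genomes)
  rep <- ani_report(am)
  expect_equal(nrow(rep$pairs), 3)
  expect_equal(min(rep$histogram$lo), 60)
  expect_equal(max(rep$histogram$hi), 100)
  expect_equal(sum(rep$histogram$count), sum(!is.na(rep$pairs$ani)))
})
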