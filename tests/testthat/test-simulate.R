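test_that("configuration invariants are enforced with named messages", {
  expect_error(sim_config(n_clones = 1), "n_clones")
  expect_error(sim_config(mean_depth = -1), "non-negative")
  expect_error(sim_config(twin_frac = 1.5), "\\[0, 1\\]")
})

test_that("a fixed seed makes the whole simulation byte-identical", {
  cfg <- small_config(seed = 404)
  a <- simulate_individual(cfg)
  b <- simulate_individual(cfg)
  expect_identical(a, b)
  c <- simulate_individual(cfg, seed = 405)
  expect_false(identical(a$truth$tree, c$truth$tree) &&
                 identical(a$truth$mutations, c$truth$mutations))
})

test_that("the lineage tree is rooted binary with the requested leaves", {
  truth <- simulate_lineage(small_config(n_clones = 13), seed = 6)
  tree <- truth$tree
  expect_equal(length(tree$samples), 13)
  expect_equal(sum(tree$branches$terminal), 13)
  # binary: every internal branch has exactly two children
  for (k in tree$branches$key[!tree$branches$terminal]) {
    expect_equal(sum(!is.na(tree$branches$parent) &
                       tree$branches$parent == k), 2)
  }
  # conservation: mutation rows match branch lengths exactly
  tab <- table(truth$mutations$branch)
  for (k in tree$branches$key) {
    n <- if (k %in% names(tab)) as.integer(tab[[k]]) else 0L
    expect_equal(n, tree$branches$n_mut[tree$branches$key == k])
  }
})

test_that("zero mutation rates give empty branches and zero event rates give no events", {
  cfg <- small_config(early_rate = c(0, 0), late_rate = c(0, 0),
                      ageing_mut_mean = 0)
  truth <- simulate_lineage(cfg, seed = 3)
  expect_true(all(truth$tree$branches$n_mut == 0))
  expect_equal(nrow(truth$mutations), 0)

  cfg2 <- small_config(sol1r_rate_by_stage = c(pregastrulation = 0,
                                               postgastrulation = 0,
                                               ageing = 0))
  truth2 <- simulate_sol1r(simulate_lineage(cfg2, seed = 3))
  expect_equal(nrow(truth2$events), 0)
})

test_that("a stage missing from the rate map is rejected", {
  cfg <- small_config(sol1r_rate_by_stage = c(ageing = 1.2))
  truth <- simulate_lineage(cfg, seed = 3)
  expect_error(simulate_sol1r(truth), "pregastrulation|postgastrulation")
})

test_that("embryonic branch mutation counts match their Poisson means", {
  # rates pinned at the upper bounds: generation 1-2 branches have mean 3.8
  # per division, so a two-generation lineage accumulates 7.6 on average
  cfg <- small_config(n_clones = 6, early_rate = c(3.8, 3.8),
                      late_rate = c(1.2, 1.2), ageing_mut_mean = 10)
  set.seed(12)
  early_counts <- unlist(lapply(1:300, function(i) {
    tr <- simulate_lineage(cfg, seed = NULL)$tree
    tr$branches$n_mut[!tr$branches$terminal & tr$branches$generation <= 2]
  }))
  mc_se <- sd(early_counts) / sqrt(length(early_counts))
  expect_lt(abs(mean(early_counts) - 3.8), 4 * mc_se)
  expect_lt(abs(2 * mean(early_counts) - 7.6), 8 * mc_se)
})

test_that("per-branch soL1R counts follow Poisson(stage rate x EPM)", {
  set.seed(44)
  cfg <- small_config(n_clones = 4, ageing_mut_mean = 2000,
                      sol1r_rate_by_stage = c(pregastrulation = 1.2,
                                              postgastrulation = 1.2,
                                              ageing = 1.2))
  counts <- numeric(0); expected <- numeric(0)
  for (i in 1:60) {
    truth <- simulate_sol1r(simulate_lineage(cfg, seed = NULL))
    term <- truth$tree$branches$key[truth$tree$branches$terminal]
    for (k in term) {
      epm <- sum(truth$mutations$endogenous[truth$mutations$branch == k])
      counts <- c(counts, sum(truth$events$branch == k))
      expected <- c(expected, 1.2 / 1000 * epm)
    }
  }
  mc_se <- sqrt(sum(expected)) / length(counts)   # Poisson variance
  expect_lt(abs(mean(counts) - mean(expected)), 4 * mc_se)
})

test_that("event class fractions match the 89:1:10 sampling weights", {
  set.seed(90)
  cfg <- small_config(n_clones = 10, ageing_mut_mean = 4000,
                      sol1r_rate_by_stage = c(pregastrulation = 1,
                                              postgastrulation = 5,
                                              ageing = 40))
  cls <- character(0)
  for (i in 1:6) {
    truth <- simulate_sol1r(simulate_lineage(cfg, seed = NULL))
    cls <- c(cls, truth$events$class)
  }
  n <- length(cls)
  expect_gt(n, 2000)
  p <- c(solo = 0.89, partnered = 0.01, orphan = 0.10)
  for (nm in names(p)) {
    frac <- mean(cls == nm)
    expect_lt(abs(frac - p[[nm]]), 3 * sqrt(p[[nm]] * (1 - p[[nm]]) / n))
  }
})

test_that("methylation counts concentrate at the epigenotype level", {
  set.seed(71)
  cfg <- small_config(n_clones = 6)
  truth <- simulate_sol1r(simulate_lineage(cfg, seed = NULL))
  obs <- simulate_observations(truth)
  st <- truth$epigenotype$clone_state
  cpg <- obs$cpg[obs$cpg$rel_pos >= 1 & obs$cpg$rel_pos <= 250, ]
  for (lev in c("open", "closed")) {
    sel <- st[cbind(cpg$clone_id, cpg$source_id)] == lev
    m <- sum(cpg$meth[sel]); tot <- sum((cpg$meth + cpg$unmeth)[sel])
    expect_gt(tot, 500)
    p0 <- cfg$epi_levels[[lev]]
    expect_lt(abs(m / tot - p0), 3 * sqrt(p0 * (1 - p0) / tot))
  }
})

test_that("clonal insertion VAF concentrates near s/(s+2r) = 1/2", {
  set.seed(72)
  cfg <- small_config(n_clones = 6, mean_depth = 30,
                      sol1r_rate_by_stage = c(pregastrulation = 2,
                                              postgastrulation = 5,
                                              ageing = 10))
  truth <- simulate_sol1r(simulate_lineage(cfg, seed = NULL))
  obs <- simulate_observations(truth)
  expect_gt(nrow(obs$insertions), 10)
  v <- insertion_vaf(obs$insertions$supporting_pairs,
                     obs$insertions$reference_pairs)
  expect_lt(abs(mean(v, na.rm = TRUE) - 0.5), 0.05)
})

test_that("observed mutation carriers mirror root-to-leaf truth, modulo dropout", {
  cfg <- small_config(n_clones = 6, ageing_mut_mean = 150)
  sim <- simulate_individual(cfg, seed = 313)
  truth <- sim$truth; obs <- sim$obs
  for (cl in truth$tree$samples) {
    path <- sample_path(truth$tree, cl)
    truth_n <- sum(truth$mutations$branch %in% path)
    observed_n <- sum(obs$vaf[truth$mutations$branch %in% path, cl] > 0,
                      na.rm = TRUE)
    expect_lte(observed_n, truth_n)
    expect_gt(observed_n, 0.97 * truth_n)  # binomial dropout at 17x is tiny
  }
})

test_that("zero-depth observation rows are emitted, not dropped", {
  cfg <- small_config(n_clones = 4, mean_depth = 2, ageing_mut_mean = 400)
  sim <- simulate_individual(cfg, seed = 500)
  expect_true(any(sim$obs$depth == 0))
  expect_equal(nrow(sim$obs$depth), nrow(sim$truth$mutations))
})

test_that("truth and observation layers stay separate", {
  sim <- simulate_individual(small_config(), seed = 62)
  expect_false(any(c("signature", "endogenous", "branch") %in%
                     names(sim$obs$mutation_info)))
  expect_false(any(c("class", "source_id", "branch") %in%
                     names(sim$obs$insertions)))
})

test_that("panel evidence fractions reproduce registry carrier frequencies", {
  set.seed(48)
  cfg <- small_config(panel_size = 400, n_sources = 10)
  truth <- simulate_sol1r(simulate_lineage(cfg, seed = NULL))
  obs <- simulate_observations(truth)
  paf_est <- compute_paf(obs$panel)
  paf_truth <- 100 * truth$registry$paf_truth
  for (s in seq_along(paf_truth)) {
    p <- truth$registry$paf_truth[s]
    expect_lt(abs(paf_est[[s]] - paf_truth[s]),
              3 * 100 * sqrt(p * (1 - p) / 400) + 2)
  }
})
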