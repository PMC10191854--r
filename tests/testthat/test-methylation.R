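test_that("CpG classification uses the 25%/75% boundaries inclusively", {
  expect_equal(classify_cpg(0.10), "homo_demethylated")
  expect_equal(classify_cpg(0.25), "heterozygous")
  expect_equal(classify_cpg(0.7499), "heterozygous")
  expect_equal(classify_cpg(0.75), "homo_methylated")
  expect_equal(classify_cpg(c(0, 1)), c("homo_demethylated", "homo_methylated"))
})

test_that("promoter score averages 0/5/10 CpG scores over +1..+250", {
  sc <- promoter_score(meth = c(9, 9, 9), unmeth = c(1, 1, 1),
                       rel_pos = c(10, 100, 200))
  expect_equal(as.numeric(sc), 10)
  sc2 <- promoter_score(meth = c(1, 5, 9), unmeth = c(9, 5, 1),
                        rel_pos = c(10, 100, 200))
  expect_equal(as.numeric(sc2), 5)
  sc3 <- promoter_score(meth = c(0, 0, 8, 3), unmeth = c(10, 10, 2, 7),
                        rel_pos = c(5, 50, 100, 200))
  expect_equal(as.numeric(sc3), 3.75)  # (0+0+10+5)/4
})

test_that("scoring excludes out-of-window and uncovered CpGs, reporting coverage", {
  sc <- promoter_score(meth = c(9, 0, 9), unmeth = c(1, 0, 1),
                       rel_pos = c(100, 150, 400))
  expect_equal(as.numeric(sc), 10)       # rel 400 outside, rel 150 uncovered
  expect_equal(attr(sc, "n_cpg"), 1L)
  expect_equal(attr(sc, "n_uncovered"), 1L)
  none <- promoter_score(meth = 0, unmeth = 0, rel_pos = 100)
  expect_true(is.na(none))
})

test_that("promoter score is order-invariant, bounded and saturates correctly", {
  set.seed(4)
  meth <- rbinom(30, 20, 0.5); unmeth <- 20 - meth
  pos <- sample(1:250, 30)
  perm <- sample(30)
  expect_equal(as.numeric(promoter_score(meth, unmeth, pos)),
               as.numeric(promoter_score(meth[perm], unmeth[perm], pos[perm])))
  s <- as.numeric(promoter_score(meth, unmeth, pos))
  expect_gte(s, 0); expect_lte(s, 10)
  expect_equal(as.numeric(promoter_score(rep(1, 5), rep(9, 5), 1:5)), 0)
  expect_equal(as.numeric(promoter_score(rep(9, 5), rep(1, 5), 1:5)), 10)
})

test_that("epigenotype categories cut the score at 2.5 and 7.5", {
  expect_equal(call_epigenotype(0), "open")
  expect_equal(call_epigenotype(5), "heterozygous")
  expect_equal(call_epigenotype(10), "closed")
  expect_equal(call_epigenotype(c(2.5, 7.5)), c("heterozygous", "closed"))
})

make_conc_tree <- function() {
  g <- data.frame(key = c("A+B+C+D", "A+B", "C+D", "A", "B", "C", "D"),
                  size = c(10L, 40L, 40L, 100L, 100L, 100L, 100L),
                  n_samples = c(4L, 2L, 2L, 1L, 1L, 1L, 1L))
  attr(g, "samples") <- LETTERS[1:4]
  class(g) <- c("mutation_groups", class(g))
  reconstruct_tree(g)
}

test_that("identical epigenotypes give full concordance and zero KS statistic", {
  tree <- make_conc_tree()
  scores <- matrix(10, 4, 3, dimnames = list(LETTERS[1:4], c("s1", "s2", "s3")))
  out <- concordance_vs_branching(tree, scores)
  expect_true(all(out$by_stratum$concordance[out$by_stratum$n_pairs > 0] == 1))
  expect_equal(out$ks$statistic, 0)
})

test_that("an open-vs-closed clone pair is fully discordant", {
  g <- data.frame(key = c("A+B", "A", "B"), size = c(5L, 50L, 50L),
                  n_samples = c(2L, 1L, 1L))
  attr(g, "samples") <- c("A", "B")
  class(g) <- c("mutation_groups", class(g))
  tree <- reconstruct_tree(g)
  scores <- matrix(c(0, 10), 2, 1, dimnames = list(c("A", "B"), "s1"))
  out <- concordance_vs_branching(tree, scores)
  expect_equal(nrow(out$pairs), 1)
  expect_false(out$pairs$concordant)
  expect_equal(out$pairs$score_diff, 10)
})

test_that("pairs are stratified by MRCA molecular time with an inclusive window", {
  # cross pairs (A-C etc.) share only the root branch: MRCA time 10;
  # within pairs (A-B, C-D) also share their cherry branch: MRCA time 50
  tree <- make_conc_tree()
  scores <- matrix(c(0, 0, 10, 10), 4, 1,
                   dimnames = list(LETTERS[1:4], "s1"))
  out <- concordance_vs_branching(tree, scores, breaks = c(5, 45))
  tab <- table(out$pairs$stratum)
  expect_equal(unname(tab[["window(5-45)"]]), 4)   # the four cross pairs
  expect_equal(unname(tab[["late(>45)"]]), 2)      # A-B and C-D
  # boundary times land inside the window (inclusive on both ends)
  out2 <- concordance_vs_branching(tree, scores, breaks = c(10, 50))
  expect_true(all(out2$pairs$stratum == "window(10-50)"))
})

test_that("epigenotypes fixed in the window are more concordant for late-branching pairs", {
  set.seed(31)
  cfg <- small_config(n_clones = 12)
  truth <- simulate_lineage(cfg, seed = 202)
  truth <- simulate_sol1r(truth)
  obs <- simulate_observations(truth)
  scores <- promoter_score_matrix(obs$cpg)
  out <- concordance_vs_branching(truth$tree, scores,
                                  breaks = cfg$gastrulation_window)
  bs <- out$by_stratum
  early <- bs$concordance[1]
  later <- bs$concordance[bs$n_pairs >= 2][sum(bs$n_pairs >= 2)]
  expect_gt(later, early)
})

test_that("flank profile difference is zero for identical groups and localized otherwise", {
  pos <- c(-500, -100, 50, 120, 500)
  cpg <- expand.grid(clone_id = c("A", "B", "C", "D"), pos = pos)
  cpg$meth <- 8; cpg$unmeth <- 2
  out <- flank_profile_diff(cpg, c("A", "B"), c("C", "D"))
  expect_true(all(out$diff == 0))

  # promoter CpGs demethylated in group 1 only
  cpg2 <- cpg
  promoter <- cpg2$pos %in% c(50, 120) & cpg2$clone_id %in% c("A", "B")
  cpg2$meth[promoter] <- 0; cpg2$unmeth[promoter] <- 10
  out2 <- flank_profile_diff(cpg2, c("A", "B"), c("C", "D"),
                             promoter_window = c(1, 250))
  expect_equal(out2$diff[out2$in_promoter], c(-0.8, -0.8))
  expect_true(all(out2$diff[!out2$in_promoter] == 0))

  # disjoint coverage -> empty profile, all positions excluded
  cpg3 <- cpg
  cpg3$meth[cpg3$clone_id %in% c("A", "B") & cpg3$pos > 0] <- 0
  cpg3$unmeth[cpg3$clone_id %in% c("A", "B") & cpg3$pos > 0] <- 0
  cpg3$meth[cpg3$clone_id %in% c("C", "D") & cpg3$pos <= 0] <- 0
  cpg3$unmeth[cpg3$clone_id %in% c("C", "D") & cpg3$pos <= 0] <- 0
  out3 <- flank_profile_diff(cpg3, c("A", "B"), c("C", "D"))
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_excluded"), length(pos))
})

test_that("readthrough FPKM follows the formula and honours ambiguity", {
  expect_equal(readthrough_fpkm(100, 1000, 10e6), 10)
  expect_equal(readthrough_fpkm(0, 1000, 10e6), 0)
  expect_true(is.na(readthrough_fpkm(100, 1000, 10e6,
                                     ambiguous_gene_context = TRUE)))
})

test_that("promoter score and readthrough FPKM are negatively associated under repression", {
  set.seed(55)
  n <- 80
  score <- runif(n, 0, 10)
  # repression model: expression scales with the demethylated allele fraction
  lam <- 50 * (1 - score / 10) + 1
  fpkm <- readthrough_fpkm(rpois(n, lam), 1000, 10e6)
  expect_lt(cor(score, fpkm, method = "spearman"), 0)
})

test_that("transduction in a clone implies a non-closed source epigenotype", {
  set.seed(17)
  cfg <- small_config(n_clones = 10,
                      sol1r_rate_by_stage = c(pregastrulation = 5,
                                              postgastrulation = 10,
                                              ageing = 5))
  truth <- simulate_sol1r(simulate_lineage(cfg, seed = 99))
  ev <- truth$events
  expect_gt(nrow(ev), 0)
  st <- truth$epigenotype$clone_state
  for (i in seq_len(nrow(ev))) {
    for (cl in key_samples_for_test(ev$branch[i])) {
      expect_true(st[cl, ev$source_id[i]] %in% c("open", "heterozygous"))
    }
  }
})
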