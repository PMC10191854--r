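test_that("variant hard filters apply each rule and log the first violation", {
  vaf <- rbind(c(0.24, 0.20, 0.10),   # never reaches 0.25
               c(0.50, 0.00, 0.45),   # clean
               c(0.50, 0.45, 0.40),   # depth 4 in one sample
               c(0.50, 0.50, 0.50),   # panel hit
               c(0.60, 0.00, 0.00))   # clipping
  depth <- rbind(c(20, 20, 20), c(20, 20, 20), c(20, 4, 20),
                 c(20, 20, 20), c(20, 20, 20))
  res <- filter_variants(vaf, depth,
                         panel_vaf = c(0, 0, 0, 0.05, 0),
                         clip_prop = c(0, 0, 0, 0, 0.8))
  expect_equal(res$keep, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  rules <- setNames(res$log$rule, res$log$variant)
  expect_equal(rules[["1"]], "max_vaf_below_threshold")
  expect_equal(rules[["3"]], "min_depth_all_samples")
  expect_equal(rules[["4"]], "panel_of_normals")
  expect_equal(rules[["5"]], "indel_clipping_proportion")
})

test_that("boundary filter values follow the stated inequalities", {
  # panel VAF exactly 1% is removed; clipping exactly 70% is kept;
  # mismatches exactly 3 removed; depth exactly 5 kept; max VAF exactly 0.25 kept
  base <- function(...) filter_variants(vaf = matrix(0.5), depth = matrix(20), ...)
  expect_false(base(panel_vaf = 0.01)$keep)
  expect_true(base(clip_prop = 0.70)$keep)
  expect_false(base(var_mismatches = 3)$keep)
  expect_true(filter_variants(matrix(0.5), matrix(5))$keep)
  expect_true(filter_variants(matrix(0.25), matrix(20))$keep)
  expect_false(filter_variants(matrix(0.249), matrix(20))$keep)
})

test_that("missing coverage is rejected with its own rule", {
  res <- filter_variants(matrix(c(0.5, 0.5), 1), matrix(c(20, NA), 1))
  expect_false(res$keep)
  expect_equal(res$log$rule, "insufficient_coverage_data")
})

test_that("filtering is order-independent", {
  set.seed(11)
  n <- 50
  vaf <- matrix(runif(n * 3), n)
  depth <- matrix(rpois(n * 3, 10), n)
  perm <- sample.int(n)
  a <- filter_variants(vaf, depth)$keep
  b <- filter_variants(vaf[perm, ], depth[perm, ])$keep
  expect_equal(b, a[perm])
})

test_that("insertion validation needs poly-A, TSD and 10% read-pair support", {
  ev <- data.frame(polyA_len = c(60, 60, 0, 60),
                   tsd_len = c(12, 12, 12, 0),
                   supporting_pairs = c(2, 10, 10, 10),
                   reference_pairs = c(38, 10, 10, 10))
  out <- validate_insertion(ev)
  expect_equal(out$valid, c(FALSE, TRUE, FALSE, FALSE))
  expect_match(out$reasons[1], "low_supporting_fraction")
  expect_match(out$reasons[3], "no_polyA")
  expect_match(out$reasons[4], "no_TSD")
  # the TSD-absent exception lets blunt insertions through, flagged
  out2 <- validate_insertion(ev[4, ], allow_tsd_absent = TRUE)
  expect_true(out2$valid)
  expect_match(out2$reasons, "tsd_absent_exception")
})

test_that("insertion VAF is s/(s+2r), undefined at zero evidence", {
  expect_equal(insertion_vaf(10, 0), 1)
  expect_equal(insertion_vaf(10, 10), 10 / 30)
  expect_equal(insertion_vaf(20, 20), insertion_vaf(10, 10))  # homogeneity
  expect_true(is.na(insertion_vaf(0, 0)))
  expect_equal(insertion_vaf(0, 10), 0)  # observed zero, not undefined
})

test_that("insertion VAF is monotone in s and antitone in r", {
  s <- 1:30
  expect_true(all(diff(insertion_vaf(s, 10)) > 0))
  expect_true(all(diff(insertion_vaf(10, s)) < 0))
})

make_sources <- function() {
  data.frame(source_id = c("X", "Y"),
             chrom = c("chr1", "chr1"),
             start = c(100000, 130000), end = c(106018, 136018),
             strand = c("+", "+"), stringsAsFactors = FALSE)
}

test_that("classification separates solo, partnered and orphan events", {
  na <- NA
  ev <- data.frame(
    # solo: both ends on L1 consensus
    insert5_contig = c("L1", "L1", na, na),
    insert5_start = c(4000, 4000, na, na),
    insert5_end = c(6019, 6019, na, na),
    insert5_strand = c("+", "+", na, na),
    # partnered: unique downstream segment 3 kb from X's 3' end
    insert3_contig = c("L1", "chr1", "chr1", "chr2"),
    insert3_start = c(5000, 109019, 114018, 5e6),
    insert3_end = c(6019, 109518, 114517, 5000499),
    insert3_strand = c("+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  out <- classify_insertion(ev, make_sources())
  expect_equal(out$class, c("solo", "partnered", "orphan", "orphan"))
  expect_equal(out$source_id[2], "X")
  expect_equal(out$source_id[3], "X")  # 8 kb downstream, attributed
  expect_true(is.na(out$source_id[4]))  # no source within 15 kb -> unknown
  expect_false(any(out$inverted[1]))
})

test_that("a segment 20 kb downstream is outside the attribution window", {
  ev <- data.frame(insert5_contig = NA, insert5_start = NA, insert5_end = NA,
                   insert5_strand = NA,
                   insert3_contig = "chr1", insert3_start = 126019,
                   insert3_end = 126518, insert3_strand = "+")
  out <- classify_insertion(ev, make_sources()[1, ])
  expect_equal(out$class, "orphan")
  expect_true(is.na(out$source_id))
})

test_that("two candidate sources resolve to the nearer 3' end, flagged ambiguous", {
  src <- data.frame(source_id = c("near", "far"), chrom = "chr1",
                    start = c(200000, 193000), end = c(206018, 199018),
                    strand = "+")
  ev <- data.frame(insert5_contig = NA, insert5_start = NA, insert5_end = NA,
                   insert5_strand = NA,
                   insert3_contig = "chr1", insert3_start = 208019,
                   insert3_end = 208318, insert3_strand = "+")
  out <- classify_insertion(ev, src)
  expect_equal(out$source_id, "near")
  expect_true(out$ambiguous_source)
})

test_that("strand-aware attribution follows the source's 3' direction", {
  src <- data.frame(source_id = "M", chrom = "chr1",
                    start = 500000, end = 506018, strand = "-")
  # on the minus strand the 3' end is `start`; transduced sequence lies at
  # lower coordinates
  ev <- data.frame(insert5_contig = NA, insert5_start = NA, insert5_end = NA,
                   insert5_strand = NA,
                   insert3_contig = "chr1", insert3_start = 495000,
                   insert3_end = 496000, insert3_strand = "-")
  out <- classify_insertion(ev, src)
  expect_equal(out$source_id, "M")
  # same offset on the wrong (downstream-coordinate) side is not attributed
  ev$insert3_start <- 510019; ev$insert3_end <- 511019
  expect_true(is.na(classify_insertion(ev, src)$source_id))
})

test_that("opposite-strand insert ends mark the event inverted", {
  ev <- data.frame(insert5_contig = "L1", insert5_start = 3000,
                   insert5_end = 4000, insert5_strand = "-",
                   insert3_contig = "L1", insert3_start = 5000,
                   insert3_end = 6019, insert3_strand = "+")
  out <- classify_insertion(ev, make_sources())
  expect_true(out$inverted)
})

test_that("mechanism flags: canonical, twin priming, extra synthesis accounting", {
  ev <- data.frame(
    chrom = "chr5", target_pos = 1e6, strand = "+",
    insert5_contig = c("L1", "L1", "L1"),
    insert5_start = c(4020, 4020, 4020), insert5_end = c(4519, 4519, 4519),
    insert5_strand = c("+", "-", "+"),
    insert3_contig = "L1", insert3_start = 5520, insert3_end = 6019,
    insert3_strand = "+",
    polyA_len = 60,
    # canonical: 500+500+60; twin: same; third: 100 unattributed bases
    insert_len = c(1060, 1060, 1160))
  out <- annotate_mechanism(ev)
  expect_equal(out$twin_priming, c(FALSE, TRUE, FALSE))
  expect_equal(out$foldback, c(FALSE, FALSE, FALSE))
  expect_equal(out$extra_synthesis_len, c(0, 0, 100))
  expect_true(out$extra_synthesis_len[3] >= 52 &&
                out$extra_synthesis_len[3] <= 220)
})

test_that("foldback requires an inverted near-breakpoint flank duplication", {
  ev <- data.frame(
    chrom = "chr5", target_pos = 1e6, strand = "+",
    insert5_contig = "L1", insert5_start = 4020, insert5_end = 4519,
    insert5_strand = "+",
    insert3_contig = "L1", insert3_start = 5520, insert3_end = 6019,
    insert3_strand = "+", polyA_len = 60, insert_len = 1110,
    flank5_contig = "chr5", flank5_start = 1e6 - 50, flank5_end = 1e6 - 1,
    flank5_strand = "-")
  out <- annotate_mechanism(ev)
  expect_true(out$foldback)
  expect_equal(out$extra_synthesis_len, 0)  # 50 bp dup accounted for
})

test_that("clonality calls use the minimum shared-event cell fraction", {
  expect_equal(reference_clonality_cutoff(c(0.7, 0.85, 0.9)), 0.7)
  out <- call_clonal_in_cancer(c(0.45, 0.15), cutoff = 0.6)
  expect_equal(out$cell_fraction, c(0.9, 0.3))
  expect_equal(out$clonal, c(TRUE, FALSE))
  expect_error(call_clonal_in_cancer(0.4, cutoff = NULL), "cutoff")
  # purity adjustment and the cap at 1
  expect_equal(call_clonal_in_cancer(0.4, 0.6, purity = 0.5)$cell_fraction, 1)
})

test_that("every validated event receives exactly one class", {
  set.seed(3)
  cfg <- small_config(sol1r_rate_by_stage = c(pregastrulation = 5,
                                              postgastrulation = 10,
                                              ageing = 10))
  sim <- simulate_individual(cfg, seed = 21)
  ins <- classify_insertion(sim$obs$insertions, sim$truth$registry)
  expect_true(all(ins$class %in% c("solo", "partnered", "orphan", "unresolved")))
  expect_equal(sum(is.na(ins$class)), 0)
})
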