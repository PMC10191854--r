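# L1 promoter CpG methylation scoring, epigenotype calls, concordance
# versus embryonic branching time, flanking profiles and readthrough FPKM.

#' Classify a CpG site by its methylated fraction
#'
#' In a clonal (single-cell-derived) genome a CpG's methylated read fraction
#' reflects its diploid state: below 25\% both alleles are demethylated, at
#' least 75\% both are methylated, in between one allele of each.
#'
#' @param fraction methylated read fraction(s) in \[0,1\].
#' @return character vector in \{"homo_demethylated", "heterozygous",
#'   "homo_methylated"\}; NA for NA input.
#' @export
classify_cpg <- function(fraction) {
  out <- rep(NA_character_, length(fraction))
  out[fraction < 0.25] <- "homo_demethylated"
  out[fraction >= 0.25 & fraction < 0.75] <- "heterozygous"
  out[fraction >= 0.75] <- "homo_methylated"
  out
}

# Per-CpG score on the 0-10 scale.
cpg_score <- function(fraction) {
  c(homo_demethylated = 0, heterozygous = 5, homo_methylated = 10)[
    classify_cpg(fraction)]
}

#' Promoter methylation score of an L1 source in one clone
#'
#' CpG sites in the scoring window (+1 to +250 relative to the L1
#' transcription start site) are each scored 0 (homozygous demethylation),
#' 5 (heterozygous) or 10 (homozygous methylation) from their methylated
#' fraction, and the promoter score is their mean. Zero-coverage CpGs are
#' excluded, not imputed, and counted in the attached coverage report.
#'
#' @param meth,unmeth integer vectors of methylated/unmethylated read counts
#'   per CpG.
#' @param rel_pos integer vector of CpG positions relative to the L1
#'   transcription start site (+1 = first base downstream).
#' @param window scoring window, default c(1, 250).
#' @return numeric score in \[0,10\] with attributes `n_cpg` (scored) and
#'   `n_uncovered` (excluded for zero coverage); `NA` when no covered CpG
#'   lies in the window.
#' @export
promoter_score <- function(meth, unmeth, rel_pos, window = c(1, 250)) {
  stopifnot(length(meth) == length(unmeth), length(meth) == length(rel_pos))
  in_win <- rel_pos >= window[1] & rel_pos <= window[2]
  cov <- meth + unmeth
  usable <- in_win & cov > 0
  n_uncovered <- sum(in_win & cov == 0)
  if (!any(usable)) {
    return(structure(NA_real_, n_cpg = 0L, n_uncovered = n_uncovered))
  }
  frac <- meth[usable] / cov[usable]
  structure(mean(cpg_score(frac)), n_cpg = sum(usable),
            n_uncovered = n_uncovered)
}

#' Promoter epigenotype category from a promoter score
#'
#' Cutoffs are the midpoints between the three pure score levels (0, 5, 10):
#' open below 2.5, heterozygous below 7.5, closed otherwise.
#'
#' @param score numeric promoter score(s) in \[0,10\].
#' @return character vector in \{"open", "heterozygous", "closed"\}.
#' @export
call_epigenotype <- function(score) {
  out <- rep(NA_character_, length(score))
  out[score < 2.5] <- "open"
  out[score >= 2.5 & score < 7.5] <- "heterozygous"
  out[score >= 7.5] <- "closed"
  out
}

#' Promoter score matrix (clone x source) from a per-CpG count table
#'
#' @param cpg data.frame with columns `clone_id`, `source_id`, `rel_pos`,
#'   `meth`, `unmeth`.
#' @param window scoring window passed to [promoter_score()].
#' @return numeric matrix, clones x sources, NA where no covered CpG.
#' @export
promoter_score_matrix <- function(cpg, window = c(1, 250)) {
  require_columns(cpg, c("clone_id", "source_id", "rel_pos", "meth", "unmeth"),
                  "cpg table")
  clones <- sort(unique(cpg$clone_id))
  sources <- sort(unique(cpg$source_id))
  out <- matrix(NA_real_, length(clones), length(sources),
                dimnames = list(clones, sources))
  idx <- split(seq_len(nrow(cpg)), list(cpg$clone_id, cpg$source_id),
               drop = TRUE)
  for (nm in names(idx)) {
    i <- idx[[nm]]
    sc <- promoter_score(cpg$meth[i], cpg$unmeth[i], cpg$rel_pos[i], window)
    out[cpg$clone_id[i][1], cpg$source_id[i][1]] <- as.numeric(sc)
  }
  out
}

#' Epigenotype concordance of clone pairs versus embryonic branching time
#'
#' For every clone pair and every (variable) source, records the absolute
#' promoter-score difference and whether the epigenotype categories agree,
#' then stratifies pairs by the molecular time of their most recent common
#' ancestor. Clone pairs that diverged after the epigenotype-fixing window
#' inherit the same promoter state and should be more concordant than pairs
#' that diverged before it. The Kolmogorov-Smirnov statistic compares the
#' score-difference distributions of the earliest and latest non-empty
#' strata.
#'
#' @param tree a `lineage_tree` for the clones.
#' @param scores clone x source promoter score matrix
#'   (see [promoter_score_matrix()]).
#' @param top_k restrict to the `top_k` sources with the largest promoter
#'   score variance across clones (default all); mirrors selecting the most
#'   variable sources.
#' @param breaks molecular-time stratum boundaries in mutations
#'   (default c(17, 65): before, within and after the fixing window).
#' @return list with `pairs` (pair-level table), `by_stratum` (stratum,
#'   n_pairs, concordance rate, mean |score diff|) and `ks`
#'   (list: statistic, p.value) comparing earliest vs latest non-empty
#'   strata (NULL when fewer than two strata have >= 2 pairs).
#' @export
concordance_vs_branching <- function(tree, scores, top_k = NULL,
                                     breaks = c(17, 65)) {
  clones <- intersect(tree$samples, rownames(scores))
  if (length(clones) < 2) stop("need >= 2 clones with epigenotypes", call. = FALSE)
  scores <- scores[clones, , drop = FALSE]
  if (!is.null(top_k) && top_k < ncol(scores)) {
    v <- apply(scores, 2L, stats::var, na.rm = TRUE)
    keep <- order(v, decreasing = TRUE)[seq_len(top_k)]
    scores <- scores[, keep, drop = FALSE]
  }
  mrca <- pair_mrca_time(tree)[clones, clones, drop = FALSE]
  cat_mat <- matrix(call_epigenotype(scores), nrow(scores),
                    dimnames = dimnames(scores))
  rows <- list()
  for (i in seq_along(clones)) for (j in seq_along(clones)) {
    if (i < j) {
      for (s in colnames(scores)) {
        a <- scores[i, s]; b <- scores[j, s]
        if (is.na(a) || is.na(b)) next
        rows[[length(rows) + 1L]] <- data.frame(
          clone1 = clones[i], clone2 = clones[j], source_id = s,
          mrca_time = mrca[i, j], score_diff = abs(a - b),
          concordant = cat_mat[i, s] == cat_mat[j, s],
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  lv <- c(sprintf("early(<%g)", breaks[1]),
          sprintf("window(%g-%g)", breaks[1], breaks[2]),
          sprintf("late(>%g)", breaks[2]))
  pairs$stratum <- cut(pairs$mrca_time, c(-Inf, breaks[1], breaks[2], Inf),
                       labels = lv, right = FALSE)
  # right=FALSE puts t == breaks[2] into the window; the window is inclusive
  pairs$stratum[pairs$mrca_time == breaks[2]] <- lv[2]
  agg <- lapply(split(pairs, pairs$stratum), function(d) {
    data.frame(n_pairs = nrow(d),
               concordance = if (nrow(d)) mean(d$concordant) else NA_real_,
               mean_score_diff = if (nrow(d)) mean(d$score_diff) else NA_real_)
  })
  by_stratum <- cbind(stratum = names(agg), do.call(rbind, agg))
  rownames(by_stratum) <- NULL
  ok <- by_stratum$n_pairs >= 2
  ks <- NULL
  if (sum(ok) >= 2) {
    lo <- by_stratum$stratum[ok][1]
    hi <- by_stratum$stratum[ok][sum(ok)]
    d1 <- pairs$score_diff[pairs$stratum == lo]
    d2 <- pairs$score_diff[pairs$stratum == hi]
    kt <- suppressWarnings(stats::ks.test(d1, d2))
    ks <- list(statistic = unname(kt$statistic), p.value = kt$p.value,
               strata = c(as.character(lo), as.character(hi)))
  }
  list(pairs = pairs, by_stratum = by_stratum, ks = ks)
}

#' Mean methylation difference profile between two clone groups
#'
#' Per shared CpG position, the mean methylated fraction in each clone group
#' and their difference; positions covered in only one group are excluded and
#' counted. Positions inside the promoter window of the source are flagged.
#'
#' @param cpg data.frame with columns `clone_id`, `pos`, `meth`, `unmeth`.
#' @param group1,group2 clone id vectors.
#' @param promoter_window length-2 numeric: positions flagged `in_promoter`
#'   (default none).
#' @return data.frame (`pos`, `mean1`, `mean2`, `diff`, `in_promoter`) with
#'   attribute `n_excluded`.
#' @export
flank_profile_diff <- function(cpg, group1, group2,
                               promoter_window = c(NA, NA)) {
  require_columns(cpg, c("clone_id", "pos", "meth", "unmeth"), "cpg table")
  mean_frac <- function(group) {
    d <- cpg[cpg$clone_id %in% group & (cpg$meth + cpg$unmeth) > 0, ,
             drop = FALSE]
    if (!nrow(d)) return(data.frame(pos = numeric(0), frac = numeric(0)))
    fr <- d$meth / (d$meth + d$unmeth)
    stats::aggregate(list(frac = fr), list(pos = d$pos), mean)
  }
  m1 <- mean_frac(group1); m2 <- mean_frac(group2)
  shared <- intersect(m1$pos, m2$pos)
  n_excluded <- length(setdiff(union(m1$pos, m2$pos), shared))
  out <- data.frame(pos = sort(shared))
  out$mean1 <- m1$frac[match(out$pos, m1$pos)]
  out$mean2 <- m2$frac[match(out$pos, m2$pos)]
  out$diff <- out$mean1 - out$mean2
  out$in_promoter <- !is.na(promoter_window[1]) &
    out$pos >= promoter_window[1] & out$pos <= promoter_window[2]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Readthrough transcription level downstream of a source element (FPKM)
#'
#' Expression of an L1 source is read out from strand-matched reads in the
#' 1 kb window downstream of its 3' end: FPKM = count / (length_kb x
#' total_mapped / 1e6). When the source sits sense within a gene, downstream
#' reads cannot be attributed and the value is undefined.
#'
#' @param read_count strand-matched read count in the downstream window.
#' @param region_length window length in bp (default 1000).
#' @param total_mapped total mapped reads in the library.
#' @param ambiguous_gene_context logical: source sense-overlapping a gene.
#' @return FPKM, or `NA` when the context is ambiguous.
#' @export
readthrough_fpkm <- function(read_count, region_length = 1000, total_mapped,
                             ambiguous_gene_context = FALSE) {
  out <- read_count / ((region_length / 1000) * (total_mapped / 1e6))
  out[ambiguous_gene_context] <- NA_real_
  out
}
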