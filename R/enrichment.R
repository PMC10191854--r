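# Genome binning by features and insertion-rate enrichment.

#' Bin a genome-wide signal track into four bins (0-3)
#'
#' Scheme-specific rules, all producing bins of (approximately) equal genomic
#' length where the scheme calls for equal-sized bins:
#' \itemize{
#'   \item `fold_enrichment`: intervals with signal below 1 form bin 0; the
#'     remainder is split by signal into three equal-bp tertiles, bin 1
#'     (least enriched) to bin 3 (most enriched).
#'   \item `expression`: intervals with no expression (signal 0) form bin 0;
#'     the remainder is split into three equal-bp tertiles by signal.
#'   \item `replication_timing`: four equal-bp quartiles of the timing
#'     signal; bin 0 holds the latest-replicating (lowest signal) quartile
#'     and bin 3 the earliest (highest signal). Supply a signal in which
#'     larger values mean earlier replication.
#' }
#' "Equal-sized" means equal genomic base pairs, since bin sizes are the
#' denominators of insertion rates.
#'
#' @param track data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `signal`.
#' @param scheme one of "fold_enrichment", "expression",
#'   "replication_timing".
#' @return the track with an added integer `bin` column (class
#'   `feature_binning`, attribute `scheme`).
#' @export
bin_signal_track <- function(track,
                             scheme = c("fold_enrichment", "expression",
                                        "replication_timing")) {
  scheme <- match.arg(scheme)
  require_columns(track, c("chrom", "start", "end", "signal"), "track")
  if (any(track$end <= track$start)) {
    stop("intervals must satisfy start < end (0-based half-open)", call. = FALSE)
  }
  if (length(unique(track$signal)) == 1L) {
    stop("degenerate track: signal is constant, binning undefined", call. = FALSE)
  }
  width <- track$end - track$start
  bin <- integer(nrow(track))
  if (scheme %in% c("fold_enrichment", "expression")) {
    zero <- if (scheme == "fold_enrichment") track$signal < 1 else track$signal == 0
    bin[zero] <- 0L
    rest <- which(!zero)
    if (!length(rest)) {
      stop("degenerate track: no intervals above the bin-0 threshold",
           call. = FALSE)
    }
    bin[rest] <- equal_bp_bins(track$signal[rest], width[rest], 3L)
  } else {
    bin <- equal_bp_bins(track$signal, width, 4L) - 1L
  }
  track$bin <- bin
  attr(track, "scheme") <- scheme
  class(track) <- c("feature_binning", class(track))
  track
}

# Split intervals into `k` groups of equal total bp by increasing signal;
# returns group index 1..k (1 = lowest signal).
equal_bp_bins <- function(signal, width, k) {
  ord <- order(signal)
  cum <- cumsum(width[ord])
  total <- cum[length(cum)]
  grp <- pmin(k, 1L + floor((cum - width[ord] / 2) / (total / k)))
  out <- integer(length(signal))
  out[ord] <- as.integer(grp)
  out
}

#' Bin genomic positions by similarity to the L1 endonuclease motif
#'
#' The L1 endonuclease nicks at a degenerate 5-bp motif, TTTT|R (R = A/G) on
#' one strand or its cleavage-equivalent Y|AAAA (Y = C/T) on the other. Each
#' position is scored by the minimum Hamming mismatch count of its 5-mer to
#' either motif, and binned: 4 or more mismatches (most dissimilar) = bin 0,
#' 3 = bin 1, 2 = bin 2, 1 or fewer (most similar) = bin 3. Ambiguous bases
#' (N) count as mismatches.
#'
#' @param seq a single genome/chromosome sequence as a character string
#'   (A/C/G/T/N).
#' @param chrom chromosome name attached to the output (default "chr1").
#' @return data.frame with `chrom`, `pos` (1-based position of the 5-mer
#'   start), `mismatches`, `bin`.
#' @export
motif_mismatch_bins <- function(seq, chrom = "chr1") {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars) - 4L
  if (n < 1L) stop("sequence shorter than the 5-bp motif", call. = FALSE)
  idx <- seq_len(n)
  base <- function(off) chars[idx + off]
  # TTTT|R
  mm1 <- (base(0) != "T") + (base(1) != "T") + (base(2) != "T") +
    (base(3) != "T") + !(base(4) %in% c("A", "G"))
  # Y|AAAA
  mm2 <- (!(base(0) %in% c("C", "T"))) + (base(1) != "A") + (base(2) != "A") +
    (base(3) != "A") + (base(4) != "A")
  mm <- pmin(mm1, mm2)
  bin <- integer(n)
  bin[mm >= 4] <- 0L
  bin[mm == 3] <- 1L
  bin[mm == 2] <- 2L
  bin[mm <= 1] <- 3L
  data.frame(chrom = chrom, pos = idx, mismatches = as.integer(mm), bin = bin)
}

# Assign insertion positions (1-based) to bins of a feature binning.
assign_bins <- function(insertions, binning) {
  require_columns(insertions, c("chrom", "pos"), "insertions")
  bin <- rep(NA_integer_, nrow(insertions))
  for (ch in unique(insertions$chrom)) {
    tr <- binning[binning$chrom == ch, , drop = FALSE]
    sel <- which(insertions$chrom == ch)
    if (!nrow(tr)) next
    ord <- order(tr$start)
    tr <- tr[ord, , drop = FALSE]
    pos0 <- insertions$pos[sel] - 1L  # to 0-based
    j <- findInterval(pos0, tr$start)
    ok <- j >= 1 & pos0 < tr$end[pmax(j, 1)]
    bin[sel[ok]] <- tr$bin[j[ok]]
  }
  bin
}

#' Insertion-rate enrichment of feature bins relative to bin 0
#'
#' The fold enrichment of bin k is its insertion density relative to bin 0:
#' (count_k / size_k) / (count_0 / size_0), with an exact conditional
#' binomial (Poisson rate-ratio) confidence interval. Bin 0 is the
#' reference, fold 1 by definition.
#'
#' @param insertions data.frame with `chrom`, `pos` (1-based).
#' @param binning a `feature_binning` (see [bin_signal_track()]).
#' @param conf confidence level (default 0.95).
#' @return data.frame per bin: `bin`, `count`, `size_bp`, `fold`,
#'   `ci_lower`, `ci_upper` (CI NA for bin 0; fold NA with a warning when
#'   bin 0 is empty of insertions).
#' @export
enrichment_scores <- function(insertions, binning, conf = 0.95) {
  bin <- assign_bins(insertions, binning)
  width <- binning$end - binning$start
  size <- vapply(0:3, function(k) sum(width[binning$bin == k]), numeric(1))
  count <- vapply(0:3, function(k) sum(bin == k, na.rm = TRUE), numeric(1))
  fold <- rep(NA_real_, 4)
  lo <- rep(NA_real_, 4); hi <- rep(NA_real_, 4)
  fold[1] <- 1
  if (count[1] == 0) {
    warning("no insertions in reference bin 0: folds undefined")
  } else {
    for (k in 2:4) {
      fold[k] <- (count[k] / size[k]) / (count[1] / size[1])
      pt <- stats::poisson.test(c(count[k], count[1]),
                                c(size[k], size[1]), conf.level = conf)
      lo[k] <- pt$conf.int[1]; hi[k] <- pt$conf.int[2]
    }
  }
  data.frame(bin = 0:3, count = count, size_bp = size,
             fold = fold, ci_lower = lo, ci_upper = hi)
}

#' Insertion counts in sliding genomic windows
#'
#' Overlapping windows (default 10 Mb, 5 Mb step) tiled per chromosome as
#' half-open intervals; each insertion is counted in every window covering
#' it. Insertions beyond the chromosome length are rejected and logged.
#'
#' @param insertions data.frame with `chrom`, `pos` (1-based).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window window size in bp (default 1e7).
#' @param step step in bp (default 5e6).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), `count`;
#'   attribute `rejected` holds out-of-range insertion rows.
#' @export
window_insertion_rate <- function(insertions, chrom_lengths,
                                  window = 1e7, step = 5e6) {
  require_columns(insertions, c("chrom", "pos"), "insertions")
  rejected <- integer(0)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    pos0 <- insertions$pos[insertions$chrom == ch] - 1
    bad <- which(insertions$chrom == ch)[pos0 >= len | pos0 < 0]
    rejected <- c(rejected, bad)
    pos0 <- pos0[pos0 < len & pos0 >= 0]
    count <- vapply(seq_along(starts), function(i)
      sum(pos0 >= starts[i] & pos0 < starts[i] + window), numeric(1))
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            count = count)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  unknown <- which(!insertions$chrom %in% names(chrom_lengths))
  attr(res, "rejected") <- sort(unique(c(rejected, unknown)))
  res
}
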