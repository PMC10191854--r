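# Validation, quantification and classification of somatic mobile-element
# insertion calls, plus the SNV/indel hard-filtering rules used upstream of
# phylogeny reconstruction.

#' Hard-filter somatic SNV/indel calls across the samples of one individual
#'
#' Applies the fixed filtering rules used to build high-confidence somatic
#' variant sets from multi-clone whole-genome data: a call is retained iff
#' (1) its panel-of-normals VAF is below 1\%, (2) the proportion of
#' indel-containing or clipped reads at the locus is at most 70\%, (3) variant
#' reads carry fewer than 3 mismatched bases, (4) depth is at least 5 in
#' every sample of the individual, and (5) VAF reaches at least 0.25 in at
#' least one sample. The first rule violated is recorded per rejected call.
#'
#' @param vaf numeric matrix, variants x samples, per-sample VAF in \[0,1\].
#' @param depth integer matrix, variants x samples, mapped read depth.
#' @param panel_vaf numeric vector, VAF of each variant in the panel of
#'   normals (default 0 = absent from the panel).
#' @param clip_prop numeric vector, proportion of indel/clipped reads at the
#'   locus (default 0).
#' @param var_mismatches numeric vector, mismatched bases in variant reads
#'   (default 0).
#' @param min_depth minimum depth required in every sample (default 5).
#' @param min_max_vaf minimum of the per-variant maximum VAF (default 0.25).
#' @param panel_max panel VAF at or above which a call is dropped (default 0.01).
#' @param clip_max clipping/indel proportion above which a call is dropped
#'   (default 0.70).
#' @param mismatch_max variant-read mismatch count at or above which a call
#'   is dropped (default 3).
#' @return list with `keep` (logical vector over variants) and `log`
#'   (data.frame of rejected variants: `variant`, `rule`).
#' @export
filter_variants <- function(vaf, depth,
                            panel_vaf = rep(0, nrow(vaf)),
                            clip_prop = rep(0, nrow(vaf)),
                            var_mismatches = rep(0, nrow(vaf)),
                            min_depth = 5, min_max_vaf = 0.25,
                            panel_max = 0.01, clip_max = 0.70,
                            mismatch_max = 3) {
  vaf <- as.matrix(vaf); depth <- as.matrix(depth)
  if (!all(dim(vaf) == dim(depth))) {
    stop("`vaf` and `depth` must have identical dimensions", call. = FALSE)
  }
  n <- nrow(vaf)
  rule <- rep(NA_character_, n)

  no_cov <- apply(depth, 1L, function(d) anyNA(d))
  rule[is.na(rule) & no_cov] <- "insufficient_coverage_data"
  rule[is.na(rule) & panel_vaf >= panel_max] <- "panel_of_normals"
  rule[is.na(rule) & clip_prop > clip_max] <- "indel_clipping_proportion"
  rule[is.na(rule) & var_mismatches >= mismatch_max] <- "variant_read_mismatches"
  low_depth <- apply(depth, 1L, function(d) any(d < min_depth))
  rule[is.na(rule) & low_depth] <- "min_depth_all_samples"
  max_vaf <- apply(vaf, 1L, max, na.rm = TRUE)
  rule[is.na(rule) & max_vaf < min_max_vaf] <- "max_vaf_below_threshold"

  keep <- is.na(rule)
  log <- data.frame(variant = which(!keep), rule = rule[!keep],
                    stringsAsFactors = FALSE)
  list(keep = keep, log = log)
}

#' Validate candidate retrotransposition insertion calls
#'
#' A call passes when the two canonical hallmarks of target-primed reverse
#' transcription are present -- a poly-A tail and a target site duplication
#' (TSD) -- and when insertion-supporting read pairs make up at least 10\% of
#' total read pairs at the locus. Blunt (TSD-absent) insertions can be let
#' through with `allow_tsd_absent = TRUE`, in which case the exception is
#' recorded in the reasons.
#'
#' @param events data.frame with columns `polyA_len`, `tsd_len`,
#'   `supporting_pairs`, `reference_pairs`.
#' @param min_support_frac minimum supporting fraction s/(s+r) (default 0.10).
#' @param allow_tsd_absent let TSD-absent events pass with a flag (default FALSE).
#' @return the events with added columns `valid` (logical) and `reasons`
#'   (comma-joined failure reasons, empty when valid).
#' @export
validate_insertion <- function(events, min_support_frac = 0.10,
                               allow_tsd_absent = FALSE) {
  require_columns(events, c("polyA_len", "tsd_len",
                            "supporting_pairs", "reference_pairs"), "events")
  s <- events$supporting_pairs
  r <- events$reference_pairs
  if (any(s < 0 | r < 0, na.rm = TRUE)) {
    stop("read-pair counts must be non-negative", call. = FALSE)
  }
  reasons <- vector("list", nrow(events))
  no_polya <- is.na(events$polyA_len) | events$polyA_len <= 0
  no_tsd <- is.na(events$tsd_len) | events$tsd_len <= 0
  total <- s + r
  low_support <- total > 0 & s < min_support_frac * total
  no_reads <- total == 0 | is.na(total)
  for (i in seq_len(nrow(events))) {
    why <- character(0)
    if (no_polya[i]) why <- c(why, "no_polyA")
    if (no_tsd[i]) why <- c(why, if (allow_tsd_absent) "tsd_absent_exception" else "no_TSD")
    if (no_reads[i]) why <- c(why, "no_informative_pairs")
    else if (low_support[i]) why <- c(why, "low_supporting_fraction")
    reasons[[i]] <- why
  }
  fail <- vapply(reasons, function(w) {
    any(!w %in% "tsd_absent_exception")
  }, logical(1))
  events$valid <- !fail
  events$reasons <- vapply(reasons, paste, character(1), collapse = ",")
  events
}

#' Variant allele fraction of an insertion from spanning read pairs
#'
#' The VAF of an insertion is the number of insertion-supporting read pairs
#' divided by the total number of informative read pairs at the site, where a
#' pair is informative if the region between its outer ends spans the
#' insertion breakpoint. Reference-supporting pairs are counted twice because
#' an insertion presents two breakpoint junctions, each independently covered
#' by supporting pairs: VAF = s / (s + 2r).
#'
#' @param s insertion-supporting read pairs (vectorized).
#' @param r reference-supporting read pairs (vectorized).
#' @return numeric VAF in \[0,1\]; `NA` where s + r = 0 (undefined, as opposed
#'   to an observed VAF of 0).
#' @export
insertion_vaf <- function(s, r) {
  if (any(s < 0 | r < 0, na.rm = TRUE)) {
    stop("read-pair counts must be non-negative", call. = FALSE)
  }
  out <- s / (s + 2 * r)
  out[(s + r) == 0] <- NA_real_
  out
}

#' Classify insertions into solo-L1, partnered and orphan transductions
#'
#' Classification is driven by what the inserted segment maps to. Mappings to
#' the L1 consensus are identified by `l1_contig`; any other contig is treated
#' as unique genomic sequence. An event is `solo` when the insert maps only to
#' L1 sequence, `partnered` when it carries L1 sequence plus a unique segment,
#' `orphan` when only a unique segment is inserted, and `unresolved` when no
#' mapping is available. Unique segments are attributed to a registered
#' full-length source element whose 3' end (in the source-strand sense) lies
#' within `max_dist` upstream of the segment; the nearest source wins, with
#' ties and multi-candidate cases flagged ambiguous. Events whose two insert
#' ends map on opposite strands are flagged inverted.
#'
#' @param events data.frame with columns `insert5_contig`, `insert5_start`,
#'   `insert5_end`, `insert5_strand`, and the same four `insert3_*` columns
#'   (NA allowed for absent mappings).
#' @param sources source registry data.frame with columns `source_id`,
#'   `chrom`, `start`, `end`, `strand` (1-based inclusive coordinates).
#' @param max_dist maximum distance from the source 3' end to the transduced
#'   segment (default 15000).
#' @param l1_contig contig name marking the L1 consensus (default "L1").
#' @return the events with added columns `class`, `inverted`, `source_id`,
#'   `source_dist`, `ambiguous_source`.
#' @export
classify_insertion <- function(events, sources, max_dist = 15000,
                               l1_contig = "L1") {
  require_columns(events, c("insert5_contig", "insert5_start", "insert5_end",
                            "insert5_strand", "insert3_contig",
                            "insert3_start", "insert3_end", "insert3_strand"),
                  "events")
  require_columns(sources, c("source_id", "chrom", "start", "end", "strand"),
                  "source registry")
  n <- nrow(events)
  class <- rep("unresolved", n)
  source_id <- rep(NA_character_, n)
  source_dist <- rep(NA_real_, n)
  ambiguous <- rep(FALSE, n)

  is_l1_5 <- !is.na(events$insert5_contig) & events$insert5_contig == l1_contig
  is_l1_3 <- !is.na(events$insert3_contig) & events$insert3_contig == l1_contig
  uniq_5 <- !is.na(events$insert5_contig) & !is_l1_5
  uniq_3 <- !is.na(events$insert3_contig) & !is_l1_3
  has_l1 <- is_l1_5 | is_l1_3
  has_uniq <- uniq_5 | uniq_3

  class[has_l1 & !has_uniq] <- "solo"
  class[has_l1 & has_uniq] <- "partnered"
  class[!has_l1 & has_uniq] <- "orphan"

  inverted <- !is.na(events$insert5_strand) & !is.na(events$insert3_strand) &
    events$insert5_strand != events$insert3_strand

  for (i in which(has_uniq)) {
    end <- if (uniq_3[i]) "insert3" else "insert5"
    seg_chrom <- events[[paste0(end, "_contig")]][i]
    seg_start <- events[[paste0(end, "_start")]][i]
    seg_end <- events[[paste0(end, "_end")]][i]
    hit <- attribute_segment(seg_chrom, seg_start, seg_end, sources, max_dist)
    source_id[i] <- hit$source_id
    source_dist[i] <- hit$distance
    ambiguous[i] <- hit$ambiguous
  }

  events$class <- class
  events$inverted <- inverted
  events$source_id <- source_id
  events$source_dist <- source_dist
  events$ambiguous_source <- ambiguous
  events
}

# Distance from a source 3' end to a putative transduced segment, in the
# source-strand sense: transduced sequence lies 3' of the source element.
attribute_segment <- function(seg_chrom, seg_start, seg_end, sources, max_dist) {
  cand <- sources[sources$chrom == seg_chrom, , drop = FALSE]
  if (!nrow(cand) || is.na(seg_start)) {
    return(list(source_id = NA_character_, distance = NA_real_, ambiguous = FALSE))
  }
  dist <- ifelse(cand$strand == "+",
                 seg_start - cand$end - 1,  # gap downstream of the 3' end
                 cand$start - seg_end - 1)  # minus strand: 3' end is `start`
  ok <- !is.na(dist) & dist >= 0 & dist <= max_dist
  if (!any(ok)) {
    return(list(source_id = NA_character_, distance = NA_real_, ambiguous = FALSE))
  }
  cand <- cand[ok, , drop = FALSE]; dist <- dist[ok]
  j <- which.min(dist)
  list(source_id = cand$source_id[j], distance = dist[j],
       ambiguous = length(dist) > 1L)
}

#' Annotate breakpoint mechanism flags on insertion events
#'
#' Infers how each insertion was resolved from the anatomy of its breakpoint
#' mappings: `twin_priming` when the insert carries an internal inversion of
#' the retrotransposed body (both insert ends map to the L1 consensus on
#' opposite strands); `foldback` when the sequence immediately 5' of the
#' insert body is an inverted duplication of the target 5' flank (a mapping
#' back to the target chromosome, near the breakpoint, on the opposite
#' strand); and `extra_synthesis_len`, the number of inserted bases accounted
#' for by neither the mapped insert segments, the poly-A tail, nor a flank
#' duplication -- attributed to additional DNA synthesis during resolution.
#'
#' @param events data.frame with the `insert5_*`/`insert3_*` mapping columns
#'   of [classify_insertion()], plus `chrom`, `target_pos`, `strand`,
#'   `polyA_len`, `insert_len`, and optional `flank5_contig`, `flank5_start`,
#'   `flank5_end`, `flank5_strand` describing where the 5'-most inserted
#'   sequence maps.
#' @param foldback_max_dist maximum distance between a flank mapping and the
#'   breakpoint for a foldback call (default 1000).
#' @param l1_contig contig name marking the L1 consensus (default "L1").
#' @return events with added columns `twin_priming`, `foldback`,
#'   `extra_synthesis_len`.
#' @export
annotate_mechanism <- function(events, foldback_max_dist = 1000,
                               l1_contig = "L1") {
  require_columns(events, c("insert5_contig", "insert5_strand",
                            "insert3_contig", "insert3_strand",
                            "chrom", "target_pos", "polyA_len", "insert_len"),
                  "events")
  n <- nrow(events)
  is_l1_5 <- !is.na(events$insert5_contig) & events$insert5_contig == l1_contig
  is_l1_3 <- !is.na(events$insert3_contig) & events$insert3_contig == l1_contig
  twin <- is_l1_5 & is_l1_3 &
    !is.na(events$insert5_strand) & !is.na(events$insert3_strand) &
    events$insert5_strand != events$insert3_strand

  has_flank <- !is.null(events$flank5_contig)
  foldback <- rep(FALSE, n)
  flank_len <- rep(0, n)
  if (has_flank) {
    fb <- !is.na(events$flank5_contig) &
      events$flank5_contig == events$chrom &
      !is.na(events$flank5_strand) &
      events$flank5_strand != events$strand &
      abs(events$flank5_start - events$target_pos) <= foldback_max_dist
    foldback <- fb & !is.na(fb)
    flank_len[foldback] <- (events$flank5_end - events$flank5_start + 1L)[foldback]
  }

  seg_len <- function(start, end) ifelse(is.na(start) | is.na(end), 0,
                                         abs(end - start) + 1L)
  accounted <- seg_len(events$insert5_start, events$insert5_end) +
    seg_len(events$insert3_start, events$insert3_end) +
    ifelse(is.na(events$polyA_len), 0, events$polyA_len) + flank_len
  extra <- pmax(0, events$insert_len - accounted)

  events$twin_priming <- twin
  events$foldback <- foldback
  events$extra_synthesis_len <- extra
  events
}

#' Minimum shared-event cell fraction used as the clonality cutoff
#'
#' Insertions shared by multiple normal clones of an individual are
#' necessarily true somatic events; the minimum cell fraction observed among
#' them anchors what a fully clonal event looks like after read sampling and
#' is used as the clonality cutoff in matched cancer samples.
#'
#' @param shared_cell_fractions numeric vector of cell fractions of validated
#'   shared events.
#' @return the minimum, a single numeric cutoff.
#' @export
reference_clonality_cutoff <- function(shared_cell_fractions) {
  if (!length(shared_cell_fractions)) {
    stop("no shared reference events: supply an explicit cutoff", call. = FALSE)
  }
  min(shared_cell_fractions)
}

#' Flag clonal insertions in a cancer sample
#'
#' The cell fraction of an autosomal event is 2 x VAF (divided by tumour
#' purity when supplied), capped at 1. An event is clonal when its cell
#' fraction reaches the reference cutoff derived from shared embryonic events
#' in normal clones (see [reference_clonality_cutoff()]).
#'
#' @param vaf numeric vector of event VAFs (see [insertion_vaf()]).
#' @param cutoff clonality cutoff on the cell-fraction scale.
#' @param purity tumour purity in (0,1\] (default 1).
#' @param ploidy_factor VAF-to-cell-fraction multiplier (default 2, autosomal
#'   heterozygous; set 1 for haploid sex chromosomes in males).
#' @return data.frame with `cell_fraction` and logical `clonal`.
#' @export
call_clonal_in_cancer <- function(vaf, cutoff, purity = 1, ploidy_factor = 2) {
  if (missing(cutoff) || is.null(cutoff) || is.na(cutoff)) {
    stop("a clonality `cutoff` must be supplied", call. = FALSE)
  }
  cf <- pmin(ploidy_factor * vaf / purity, 1)
  data.frame(cell_fraction = cf, clonal = cf >= cutoff)
}
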