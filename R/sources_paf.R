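# Source-element fingerprinting, per-allele activity (TPAM), population
# allele frequency, and truncation classification.

#' Fingerprint a transduced segment to its source element
#'
#' A 3' transduction carries unique sequence from immediately downstream of
#' its source element, so a uniquely mapped transduced segment identifies the
#' source: the registered element whose 3' end (in the source-strand sense)
#' lies within `max_dist` upstream of the segment. The nearest source wins;
#' multiple candidates are flagged ambiguous. Segments flagged as mapping
#' inside an annotated repeat are refused.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optional logical `in_repeat`.
#' @param registry source registry with `source_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param max_dist attribution window in bp (default 15000).
#' @return data.frame with `source_id` (NA = unknown), `distance`,
#'   `ambiguous`, `reason`.
#' @export
fingerprint <- function(segments, registry, max_dist = 15000) {
  require_columns(segments, c("chrom", "start", "end"), "segments")
  require_columns(registry, c("source_id", "chrom", "start", "end", "strand"),
                  "registry")
  n <- nrow(segments)
  out <- data.frame(source_id = rep(NA_character_, n),
                    distance = rep(NA_real_, n),
                    ambiguous = rep(FALSE, n),
                    reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  in_repeat <- segments$in_repeat %||% rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(in_repeat[i])) {
      out$reason[i] <- "segment_in_repeat"
      next
    }
    hit <- attribute_segment(segments$chrom[i], segments$start[i],
                             segments$end[i], registry, max_dist)
    out$source_id[i] <- hit$source_id
    out$distance[i] <- hit$distance
    out$ambiguous[i] <- hit$ambiguous
    if (is.na(hit$source_id)) out$reason[i] <- "no_source_within_window"
  }
  out
}

#' Transductions per L1 allele per 1 million EPMs (TPAM)
#'
#' Per-source activity normalized by both germline dosage and molecular
#' time: only individuals harbouring the source contribute, and exposures
#' are pooled (ratio of sums) across carriers, which is unbiased under
#' Poisson event counts. TPAM = sum(events) / sum(alleles x EPM / 1e6).
#'
#' @param transductions per-individual transduction counts from the source.
#' @param alleles per-individual allele counts (zygosity 0/1/2; postzygotic
#'   sources count 1 in carrier lineages).
#' @param epm per-individual total EPM over the normal lineages examined.
#' @return single TPAM value; `NA` when no carrier exposure exists.
#' @export
compute_tpam <- function(transductions, alleles, epm) {
  if (!(length(transductions) == length(alleles) &&
        length(alleles) == length(epm))) {
    stop("per-individual vectors must have equal length", call. = FALSE)
  }
  carrier <- alleles > 0
  exposure <- sum(alleles[carrier] * epm[carrier]) / 1e6
  if (exposure <= 0) return(NA_real_)
  sum(transductions[carrier]) / exposure
}

#' Call source presence in an individual from supporting-read evidence
#'
#' Presence evidence is the proportion of L1-supporting reads (non-reference
#' sources) or of short-insert, deletion-opposing reads (reference sources);
#' an individual carries the source when the proportion is at least 15\%.
#'
#' @param evidence_fraction numeric vector of per-individual proportions.
#' @param min_fraction presence threshold (default 0.15).
#' @return logical vector.
#' @export
call_presence <- function(evidence_fraction, min_fraction = 0.15) {
  evidence_fraction >= min_fraction
}

#' Population allele frequency of source elements
#'
#' PAF is the percentage of panel individuals carrying the source.
#'
#' @param panel matrix or data.frame, individuals x sources, of presence
#'   evidence fractions (or logical presence calls).
#' @param min_fraction presence threshold passed to [call_presence()].
#' @return named numeric vector of PAF percentages per source.
#' @export
compute_paf <- function(panel, min_fraction = 0.15) {
  panel <- as.matrix(panel)
  if (!nrow(panel)) stop("empty panel: PAF undefined", call. = FALSE)
  present <- if (is.logical(panel)) panel else call_presence(panel, min_fraction)
  100 * colMeans(present)
}

#' Default open reading frame annotation of the L1HS consensus
#'
#' ORF intervals on the 6,019 bp L1HS consensus, shipped as a plain-text
#' annotation and used by [classify_truncation()] when no custom annotation
#' is supplied.
#'
#' @return data.frame with `orf`, `start`, `end` (1-based consensus
#'   coordinates).
#' @export
l1_orf_annotation <- function() {
  path <- system.file("extdata", "l1hs_orfs.tsv", package = "l1mosaic")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Classify a source element as intact or ORF-truncated
#'
#' A source is truncated when every informative allele carries at least one
#' ORF-disrupting variant: a stop-introducing substitution or a frameshifting
#' (length not a multiple of 3) indel inside an ORF interval. In-frame indels
#' and synonymous/missense substitutions do not truncate. With no informative
#' allele the status is unknown.
#'
#' @param variants data.frame of variants on the element consensus with
#'   columns `allele` (identifier of the haplotype observed), `pos` (1-based
#'   consensus coordinate), `ref`, `alt`, and optional logical `stop_gained`
#'   for substitutions.
#' @param orfs ORF intervals (`orf`, `start`, `end`); defaults to
#'   [l1_orf_annotation()].
#' @param n_alleles number of informative alleles examined; alleles listed in
#'   `variants` but carrying no truncating variant keep the element intact.
#' @return one of "truncated", "intact", "unknown".
#' @export
classify_truncation <- function(variants, orfs = NULL, n_alleles = NULL) {
  if (is.null(orfs)) {
    orfs <- tryCatch(l1_orf_annotation(), error = function(e) NULL)
    if (is.null(orfs)) {
      warning("no ORF annotation available: truncation status unknown")
      return("unknown")
    }
  }
  alleles <- unique(variants$allele)
  if (is.null(n_alleles)) n_alleles <- length(alleles)
  if (n_alleles == 0) return("unknown")
  in_orf <- vapply(variants$pos, function(p)
    any(p >= orfs$start & p <= orfs$end), logical(1))
  indel_shift <- (nchar(variants$alt) - nchar(variants$ref)) %% 3 != 0
  stopg <- variants$stop_gained %||% rep(FALSE, nrow(variants))
  stopg[is.na(stopg)] <- FALSE
  truncating <- in_orf & (indel_shift | stopg)
  hit_alleles <- unique(variants$allele[truncating])
  if (length(hit_alleles) >= n_alleles && n_alleles > 0) "truncated" else "intact"
}
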