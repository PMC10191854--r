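# Developmental staging of branches, endogenous point mutation (EPM)
# counting via signature refitting, and soL1R rate estimation/comparison.

#' Refit mutational signature exposures by non-negative least squares
#'
#' Given an observed mutation spectrum and a reference signature matrix
#' (channels x signatures, columns summing to 1), finds the non-negative
#' exposure vector minimizing the squared reconstruction error. This is a
#' refit against known signatures; de novo signature discovery is out of
#' scope.
#'
#' @param spectrum numeric vector of channel counts.
#' @param signatures numeric matrix, channels x signatures, each column a
#'   probability distribution over channels.
#' @return list with `exposures` (named non-negative vector) and `residual`
#'   (Euclidean norm of the reconstruction error).
#' @export
fit_signature_exposures <- function(spectrum, signatures) {
  signatures <- as.matrix(signatures)
  if (length(spectrum) != nrow(signatures)) {
    stop("spectrum length must equal the number of signature channels",
         call. = FALSE)
  }
  csum <- colSums(signatures)
  if (any(abs(csum - 1) > 1e-6)) {
    stop("signature columns must sum to 1", call. = FALSE)
  }
  if (all(spectrum == 0)) {
    return(list(exposures = stats::setNames(rep(0, ncol(signatures)),
                                            colnames(signatures)),
                residual = 0))
  }
  fit <- pracma::lsqnonneg(signatures, as.numeric(spectrum))
  list(exposures = stats::setNames(fit$x, colnames(signatures)),
       residual = sqrt(sum(fit$resid.norm)))
}

#' Count endogenous point mutations (EPMs) from signature exposures
#'
#' EPMs are the molecular clock used to normalize retrotransposition rates:
#' SNVs attributed to SBS1 and SBS5/40 plus indels attributed to ID1 and ID2.
#' Exposures are kept real-valued internally and rounded only here, where a
#' count is needed.
#'
#' @param exposures named numeric vector of signature exposures (SNV and
#'   indel exposures may be concatenated).
#' @param endogenous signature names counted as endogenous.
#' @return integer EPM count.
#' @export
count_epm <- function(exposures,
                      endogenous = c("SBS1", "SBS5", "SBS40", "SBS5/40",
                                     "ID1", "ID2")) {
  round(sum(exposures[names(exposures) %in% endogenous]))
}

#' Assign developmental stages to tree branches
#'
#' Shared (internal) branches whose mutations are detected in bulk blood are
#' pregastrulational: blood is mesodermal, colorectal epithelium endodermal,
#' so cross-germ-layer detection places the mutation before germ-layer
#' separation. Shared branches without blood evidence are postgastrulational.
#' Terminal branches of normal clones accumulate during ageing; the clonal
#' branch of a matched cancer is tumourigenesis.
#'
#' @param tree a `lineage_tree`.
#' @param blood_detected named logical vector keyed by branch key: TRUE when
#'   the branch's shared mutations are found in bulk blood. NULL (no blood
#'   data) defaults all shared branches to postgastrulation, with a warning.
#' @param cancer_samples sample ids whose terminal branches represent the
#'   clonal expansion of a cancer (default none).
#' @return the tree with the `stage` column filled; stages partition all
#'   branches.
#' @export
assign_stages <- function(tree, blood_detected = NULL,
                          cancer_samples = character(0)) {
  b <- tree$branches
  stage <- rep(NA_character_, nrow(b))
  shared <- !b$terminal
  if (is.null(blood_detected)) {
    if (any(shared)) {
      warning("no blood evidence supplied: shared branches set to postgastrulation")
    }
    stage[shared] <- "postgastrulation"
  } else {
    in_blood <- stats::setNames(rep(FALSE, nrow(b)), b$key)
    in_blood[names(blood_detected)] <- blood_detected
    stage[shared & in_blood[b$key]] <- "pregastrulation"
    stage[shared & !in_blood[b$key]] <- "postgastrulation"
  }
  term_sample <- vapply(b$key, function(k) {
    s <- key_samples(k); if (length(s) == 1L) s else NA_character_
  }, character(1))
  stage[b$terminal & !(term_sample %in% cancer_samples)] <- "ageing"
  stage[b$terminal & (term_sample %in% cancer_samples)] <- "tumourigenesis"
  tree$branches$stage <- stage
  tree
}

#' soL1R rate per 1,000 EPMs with exact Poisson confidence interval
#'
#' The rate is the soL1R event count divided by the EPM exposure, scaled to
#' events per 1,000 EPMs. The 95\% interval is the exact Poisson
#' (chi-square quantile) interval on the event count divided by the
#' exposure: lower = qchisq(a/2, 2x)/2, upper = qchisq(1-a/2, 2x+2)/2.
#'
#' @param events non-negative event count.
#' @param epm positive EPM exposure.
#' @param conf confidence level (default 0.95).
#' @return data.frame of class `rate_estimate`: `events`, `epm`, `rate`
#'   (per 1,000 EPMs), `ci_lower`, `ci_upper`.
#' @export
sol1r_rate <- function(events, epm, conf = 0.95) {
  if (length(epm) != 1 || is.na(epm) || epm <= 0) {
    stop("`epm` must be a single positive exposure; rate is undefined at 0",
         call. = FALSE)
  }
  if (events < 0) stop("`events` must be non-negative", call. = FALSE)
  a <- 1 - conf
  lower <- if (events == 0) 0 else stats::qchisq(a / 2, 2 * events) / 2
  upper <- stats::qchisq(1 - a / 2, 2 * events + 2) / 2
  out <- data.frame(events = events, epm = epm,
                    rate = 1000 * events / epm,
                    ci_lower = 1000 * lower / epm,
                    ci_upper = 1000 * upper / epm)
  class(out) <- c("rate_estimate", class(out))
  out
}

#' Two-sided exact Poisson test comparing two soL1R rates
#'
#' Conditional on the total event count, the count in group 1 is binomial
#' with success probability epm1/(epm1+epm2) under the null of equal rates;
#' the two-sided p-value sums the probabilities of all outcomes no more
#' likely than the observed one (the standard exact binomial test).
#'
#' @param events1,events2 event counts.
#' @param epm1,epm2 positive EPM exposures.
#' @return two-sided p-value.
#' @export
compare_rates <- function(events1, epm1, events2, epm2) {
  if (epm1 <= 0 || epm2 <= 0) stop("exposures must be positive", call. = FALSE)
  total <- events1 + events2
  if (total == 0) return(1)
  stats::binom.test(events1, total, p = epm1 / (epm1 + epm2))$p.value
}

#' Convert molecular time to a cell-generation range
#'
#' Embryonic molecular time (postzygotic mutation count) is converted to
#' physical cell generations using stage-specific per-division mutation
#' rates: 2.4-3.8 mutations per cell per cell division (pcpcd) for the first
#' two divisions, then 0.7-1.2 pcpcd. For a rate pair (r1, r2) the generation
#' is m/r1 when m <= 2 r1, else 2 + (m - 2 r1)/r2. The fast pair (3.8, 1.2)
#' gives the earliest consistent generation; the slow pair (2.4, 0.7) the
#' latest.
#'
#' @param m non-negative molecular time(s), in mutations.
#' @param fast,slow rate pairs c(first-two-divisions, later) in pcpcd.
#' @return data.frame with columns `earliest` and `latest` (rounded
#'   generations).
#' @export
molecular_time_to_generations <- function(m, fast = c(3.8, 1.2),
                                          slow = c(2.4, 0.7)) {
  if (any(m < 0)) stop("molecular time must be non-negative", call. = FALSE)
  gen <- function(m, r) ifelse(m <= 2 * r[1], m / r[1],
                               2 + (m - 2 * r[1]) / r[2])
  data.frame(earliest = round(gen(m, fast)), latest = round(gen(m, slow)))
}

#' Regression of mean soL1R burden per clone on donor age
#'
#' Ordinary least squares of the per-individual mean burden on age; no
#' automatic outlier exclusion (outliers are the analyst's call).
#'
#' @param burden numeric vector, mean soL1R count per clone per individual.
#' @param age numeric vector of ages in years.
#' @param conf confidence level (default 0.95).
#' @return list with `slope` (events per clone per year), `ci` (length-2),
#'   `intercept`, and the fitted `model`.
#' @export
burden_age_regression <- function(burden, age, conf = 0.95) {
  if (length(burden) < 3) stop("at least 3 individuals required", call. = FALSE)
  if (length(unique(age)) == 1L) {
    stop("all ages identical: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(burden ~ age)
  ci <- stats::confint(fit, "age", level = conf)
  list(slope = unname(stats::coef(fit)["age"]),
       ci = as.numeric(ci),
       intercept = unname(stats::coef(fit)[1]),
       model = fit)
}
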