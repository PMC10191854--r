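# Synthetic-data generator: emulates the statistical structure of clonal
# whole-genome data (embryonic lineage tree with stage-specific Poisson
# mutation accumulation, stage-specific soL1R occurrence from a registry of
# heterogeneously active sources, clonal VAF structure with read-sampling
# noise, bimodal promoter methylation fixed near gastrulation, and a
# population presence panel), so that every downstream stage of the pipeline
# is testable without controlled-access data. Truth and observations are
# kept strictly separate.

#' Simulation configuration
#'
#' Defaults encode the study conditions of normal colorectal clones: 2.4-3.8
#' mutations per cell per cell division (pcpcd) for the first two divisions
#' and 0.7-1.2 pcpcd thereafter; stage-specific soL1R rates of 1.06
#' (pregastrulation), 4.52 (postgastrulation) and 1.2 (ageing) events per
#' 1,000 EPMs; insertion class weights 89:1:10 (solo:partnered:orphan); a
#' 29.5\% twin-priming and 0.3\% foldback fraction; sequencing depth 17x;
#' promoter methylation levels 0.05/0.5/0.95 for open/heterozygous/closed
#' epigenotypes fixed in the 17-65 mutation window of molecular time; and
#' insertion target sites enriched 5.89-fold in the latest-replicating
#' quarter of the genome.
#'
#' @param n_clones clones per individual (>= 2).
#' @param n_individuals individuals in the cohort.
#' @param early_rate,late_rate pcpcd ranges c(low, high) for generations 1-2
#'   and thereafter.
#' @param late_gens_per_branch cell generations spanned by each
#'   postgastrulation internal branch.
#' @param ageing_mut_mean mean total somatic mutations on a terminal (ageing)
#'   branch of an adult colorectal clone.
#' @param sol1r_rate_by_stage named events-per-1,000-EPM rates.
#' @param class_weights solo/partnered/orphan sampling weights.
#' @param twin_frac,foldback_frac fractions of events resolved by twin
#'   priming / with 5'-flank foldback plus extra synthesis.
#' @param extra_synthesis_range bp range of unattributed extra synthesis on
#'   foldback events.
#' @param mean_depth mean WGS depth per clone.
#' @param meth_depth mean methylation-sequencing CpG coverage.
#' @param n_sources source elements in the registry.
#' @param n_cpg CpG sites simulated in the +1..+250 promoter window.
#' @param epi_levels methylated fraction by epigenotype.
#' @param gastrulation_window molecular-time window (mutations) in which the
#'   promoter epigenotype of each source is fixed.
#' @param snv_frac fraction of mutations that are SNVs.
#' @param endog_snv_frac,endog_indel_frac endogenous (SBS1+SBS5/40, ID1+ID2)
#'   fractions among SNVs / indels.
#' @param chrom_lengths toy genome chromosome lengths (bp).
#' @param target_bin_weights insertion preference per replication-timing bin
#'   0-3 (bin 0 = latest replicating).
#' @param panel_size individuals in the population presence panel.
#' @param seed integer seed; fixed seed implies byte-identical outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 20,
                       n_individuals = 19,
                       early_rate = c(2.4, 3.8),
                       late_rate = c(0.7, 1.2),
                       late_gens_per_branch = 10,
                       ageing_mut_mean = 2500,
                       sol1r_rate_by_stage = c(pregastrulation = 1.06,
                                               postgastrulation = 4.52,
                                               ageing = 1.2),
                       class_weights = c(solo = 0.89, partnered = 0.01,
                                         orphan = 0.10),
                       twin_frac = 0.295,
                       foldback_frac = 0.003,
                       extra_synthesis_range = c(52, 220),
                       mean_depth = 17,
                       meth_depth = 20,
                       n_sources = 34,
                       n_cpg = 12,
                       epi_levels = c(open = 0.05, heterozygous = 0.5,
                                      closed = 0.95),
                       gastrulation_window = c(17, 65),
                       snv_frac = 0.9,
                       endog_snv_frac = 0.8,
                       endog_indel_frac = 0.9,
                       chrom_lengths = c(chr1 = 1e8, chr2 = 8e7, chr3 = 6e7),
                       target_bin_weights = c(5.89, 1, 1, 1),
                       panel_size = 100,
                       seed = NULL) {
  cfg <- as.list(environment())
  if (!is.numeric(n_clones) || n_clones < 2) {
    stop("`n_clones` must be at least 2", call. = FALSE)
  }
  if (any(c(early_rate, late_rate, sol1r_rate_by_stage, ageing_mut_mean,
            mean_depth, meth_depth, target_bin_weights) < 0)) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  all_probs <- c(class_weights / sum(class_weights), twin_frac, foldback_frac,
                 epi_levels, snv_frac, endog_snv_frac, endog_indel_frac)
  if (any(all_probs < 0 | all_probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic reference mutational-signature matrices
#'
#' Deterministic peaked channel distributions standing in for the COSMIC
#' reference in simulations and refitting tests: four SNV signatures over 96
#' trinucleotide channels (SBS1, the combined clock-like SBS5/40, SBS18 and
#' a flat residual) and three indel signatures over 12 channels (ID1, ID2,
#' residual). Signatures are synthetic: their channel shapes are arbitrary
#' but mutually distinguishable; only their names carry meaning.
#'
#' @return list with matrices `snv` (96 x 4) and `indel` (12 x 3), columns
#'   summing to 1.
#' @export
synthetic_signatures <- function() {
  peak <- function(n, center, width, floor = 0.1) {
    x <- exp(-((seq_len(n) - center)^2) / (2 * width^2)) + floor / n
    x / sum(x)
  }
  snv <- cbind(`SBS1` = peak(96, 12, 3),
               `SBS5/40` = peak(96, 48, 20),
               `SBS18` = peak(96, 80, 4),
               `SBSother` = rep(1 / 96, 96))
  indel <- cbind(`ID1` = peak(12, 3, 1),
                 `ID2` = peak(12, 9, 1),
                 `IDother` = rep(1 / 12, 12))
  list(snv = snv, indel = indel)
}

#' Deterministic synthetic replication-timing track for the toy genome
#'
#' A smooth sinusoidal timing signal over 1 Mb intervals (larger = earlier
#' replication), used to bias simulated insertion sites and to exercise the
#' enrichment module. Deterministic: no random numbers.
#'
#' @param chrom_lengths named chromosome lengths.
#' @param interval interval width in bp (default 1e6).
#' @return a `feature_binning` track (scheme "replication_timing").
#' @export
synthetic_timing_track <- function(chrom_lengths, interval = 1e6) {
  rows <- lapply(seq_along(chrom_lengths), function(ci) {
    len <- chrom_lengths[[ci]]
    starts <- seq(0, len - 1, by = interval)
    ends <- pmin(starts + interval, len)
    signal <- 50 + 45 * sin(starts / 7.3e6 + ci)
    data.frame(chrom = names(chrom_lengths)[ci], start = starts, end = ends,
               signal = signal)
  })
  bin_signal_track(do.call(rbind, rows), scheme = "replication_timing")
}

#' Simulate a registry of L1 source elements
#'
#' Sources receive a population allele frequency from a three-component
#' mixture (prevalent, intermediate, rare/private) and an activity weight
#' inversely related to PAF, except for a handful of "prevalent-active"
#' sources that escape repression -- the qualitative structure observed for
#' retrotransposition-competent L1s.
#'
#' @param config a `sim_config`.
#' @param seed optional integer seed.
#' @return data.frame: `source_id`, `chrom`, `start`, `end`, `strand`,
#'   `reference_status`, `paf_truth` (carrier probability), `activity`,
#'   `prevalent_active`, `p_open` (probability the promoter epigenotype fixes
#'   open).
#' @export
simulate_registry <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_sources
  tier <- sample(c("prevalent", "intermediate", "rare"), n, replace = TRUE,
                 prob = c(0.4, 0.35, 0.25))
  paf <- numeric(n)
  paf[tier == "prevalent"] <- runif(sum(tier == "prevalent"), 0.85, 1)
  paf[tier == "intermediate"] <- runif(sum(tier == "intermediate"), 0.25, 0.75)
  paf[tier == "rare"] <- runif(sum(tier == "rare"), 0.005, 0.10)
  activity <- exp(stats::rnorm(n, 0, 0.5)) * (1.1 - paf)
  prevalent_active <- rep(FALSE, n)
  pa <- which(tier == "prevalent")
  if (length(pa)) {
    pa <- pa[seq_len(min(4, length(pa)))]
    prevalent_active[pa] <- TRUE
    activity[pa] <- activity[pa] * 25
  }
  chrom <- sample(names(config$chrom_lengths), n, replace = TRUE)
  start <- vapply(chrom, function(ch)
    floor(runif(1, 1, config$chrom_lengths[[ch]] - 2e4)), numeric(1))
  data.frame(
    source_id = sprintf("src%02d", seq_len(n)),
    chrom = chrom, start = as.numeric(start),
    end = as.numeric(start) + 6018, strand = sample(c("+", "-"), n, TRUE),
    reference_status = sample(c("referenced", "non-referenced"), n, TRUE,
                              prob = c(0.7, 0.3)),
    paf_truth = paf, activity = activity,
    prevalent_active = prevalent_active,
    p_open = pmin(0.95, pmax(0.05, 0.15 + 0.6 * (1 - paf) +
                               ifelse(prevalent_active, 0.6, 0))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate an embryonic lineage tree with mutation accumulation
#'
#' Builds a rooted binary tree over `n_clones` clones by uniformly random
#' splits. Internal branches at generations 1-2 span one cell division at an
#' early pcpcd rate drawn uniformly from `early_rate`; deeper internal
#' branches span `late_gens_per_branch` divisions at a rate from
#' `late_rate`; terminal branches carry Poisson(`ageing_mut_mean`) lifetime
#' mutations. Branch mutation counts are Poisson with mean = generations
#' spanned x per-generation rate. Each mutation gets a type (SNV/indel), a
#' signature label and an observable spectrum channel drawn from the
#' synthetic reference signatures, and genomic coordinates.
#'
#' @param config a `sim_config`.
#' @param seed optional integer seed (defaults to `config$seed`).
#' @return list of class `sim_truth`: `tree` (a `lineage_tree` with truth
#'   stages filled), `mutations` (data.frame: `mut_id`, `branch`, `type`,
#'   `signature`, `endogenous`, `channel`, `chrom`, `pos`), `registry`
#'   (NULL until [simulate_sol1r()]), `config`.
#' @export
simulate_lineage <- function(config, seed = config$seed) {
  if (config$n_clones < 2) stop("`n_clones` must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  clones <- sprintf("C%02d", seq_len(config$n_clones))

  branches <- list()
  recurse <- function(set, gen) {
    key <- sample_key(set)
    terminal <- length(set) == 1L
    branches[[length(branches) + 1L]] <<- list(key = key, gen = gen,
                                               terminal = terminal)
    if (!terminal) {
      k <- sample.int(length(set) - 1L, 1L)
      left <- sample(set, k)
      recurse(left, gen + 1L)
      recurse(setdiff(set, left), gen + 1L)
    }
  }
  k <- sample.int(length(clones) - 1L, 1L)
  left <- sample(clones, k)
  recurse(left, 1L)
  recurse(setdiff(clones, left), 1L)

  b <- do.call(rbind, lapply(branches, function(x)
    data.frame(key = x$key, gen = x$gen, terminal = x$terminal,
               stringsAsFactors = FALSE)))
  b$stage <- ifelse(b$terminal, "ageing",
                    ifelse(b$gen <= 2, "pregastrulation", "postgastrulation"))
  b$gens_spanned <- ifelse(b$terminal, NA_real_,
                           ifelse(b$gen <= 2, 1, config$late_gens_per_branch))
  mean_mut <- numeric(nrow(b))
  for (i in seq_len(nrow(b))) {
    if (b$terminal[i]) {
      mean_mut[i] <- config$ageing_mut_mean
    } else {
      range <- if (b$gen[i] <= 2) config$early_rate else config$late_rate
      mean_mut[i] <- b$gens_spanned[i] * runif(1, range[1], range[2])
    }
  }
  b$n_mut <- stats::rpois(nrow(b), mean_mut)

  # parent keys from subset containment
  sets <- lapply(b$key, key_samples)
  card <- lengths(sets)
  b$parent <- vapply(seq_len(nrow(b)), function(i) {
    sup <- which(card > card[i] &
                   vapply(sets, function(a) all(sets[[i]] %in% a), logical(1)))
    if (!length(sup)) return(NA_character_)
    b$key[sup[which.min(card[sup])]]
  }, character(1))

  tree <- structure(list(
    samples = clones,
    branches = data.frame(key = b$key, parent = b$parent,
                          n_mut = as.numeric(b$n_mut), terminal = b$terminal,
                          stage = b$stage, generation = b$gen,
                          stringsAsFactors = FALSE),
    discarded = data.frame(key = character(0), size = integer(0))),
    class = "lineage_tree")

  mutations <- simulate_mutation_table(tree, config)
  structure(list(tree = tree, mutations = mutations, registry = NULL,
                 config = config),
            class = "sim_truth")
}

# Per-branch mutation records with signature labels and spectrum channels.
simulate_mutation_table <- function(tree, config) {
  sigs <- synthetic_signatures()
  rows <- list()
  for (i in seq_len(nrow(tree$branches))) {
    n <- tree$branches$n_mut[i]
    if (n == 0) next
    is_snv <- runif(n) < config$snv_frac
    signature <- character(n)
    channel <- integer(n)
    ns <- sum(is_snv)
    if (ns) {
      endo <- runif(ns) < config$endog_snv_frac
      sig <- ifelse(endo,
                    sample(c("SBS1", "SBS5/40"), ns, TRUE, prob = c(0.45, 0.55)),
                    sample(c("SBS18", "SBSother"), ns, TRUE, prob = c(0.6, 0.4)))
      signature[is_snv] <- sig
      ch <- integer(ns)
      for (sg in unique(sig)) {
        j <- sig == sg
        ch[j] <- sample.int(96, sum(j), replace = TRUE, prob = sigs$snv[, sg])
      }
      channel[is_snv] <- ch
    }
    ni <- n - ns
    if (ni) {
      endo <- runif(ni) < config$endog_indel_frac
      sig <- ifelse(endo, sample(c("ID1", "ID2"), ni, TRUE), "IDother")
      signature[!is_snv] <- sig
      ch <- integer(ni)
      for (sg in unique(sig)) {
        j <- sig == sg
        ch[j] <- sample.int(12, sum(j), replace = TRUE, prob = sigs$indel[, sg])
      }
      channel[!is_snv] <- ch
    }
    chrom <- sample(names(config$chrom_lengths), n, replace = TRUE,
                    prob = unlist(config$chrom_lengths))
    pos <- floor(runif(n, 1, unlist(config$chrom_lengths)[chrom]))
    rows[[length(rows) + 1L]] <- data.frame(
      branch = tree$branches$key[i],
      type = ifelse(is_snv, "SNV", "indel"),
      signature = signature,
      endogenous = signature %in% c("SBS1", "SBS5/40", "ID1", "ID2"),
      channel = channel, chrom = chrom, pos = pos,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(branch = character(0), type = character(0),
                      signature = character(0), endogenous = logical(0),
                      channel = integer(0), chrom = character(0),
                      pos = numeric(0))
  }
  out$mut_id <- if (nrow(out)) sprintf("m%06d", seq_len(nrow(out))) else character(0)
  rownames(out) <- NULL
  out
}

# Cumulative molecular time at the start of every branch (truth tree).
branch_start_times <- function(tree) {
  b <- tree$branches
  t0 <- stats::setNames(rep(NA_real_, nrow(b)), b$key)
  remaining <- b$key
  while (length(remaining)) {
    for (k in remaining) {
      p <- b$parent[b$key == k]
      if (is.na(p)) {
        t0[k] <- 0
      } else if (!is.na(t0[p])) {
        t0[k] <- t0[p] + b$n_mut[b$key == p]
      }
    }
    remaining <- names(t0)[is.na(t0)]
  }
  t0
}

#' Simulate promoter epigenotypes fixed near gastrulation
#'
#' For each source a fixation time is drawn uniformly inside the
#' gastrulation window; lineages are "open" (globally demethylated) before
#' that molecular time, and the first branch of each lineage to cross it
#' draws the source's epigenotype once (open with probability `p_open` from
#' the registry, otherwise heterozygous or closed), after which descendants
#' inherit it. Clone pairs diverging after fixation therefore share
#' epigenotypes; pairs diverging before it draw independently.
#'
#' @param truth a `sim_truth` with `registry` attached.
#' @param seed optional integer seed.
#' @return the truth with `epigenotype` added: a list with `fix_time` (per
#'   source) and `state` (branch x source matrix of
#'   open/heterozygous/closed) plus `clone_state` (clone x source).
#' @export
simulate_epigenotypes <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- truth$config
  reg <- truth$registry
  if (is.null(reg)) stop("attach a registry first (simulate_sol1r/simulate_registry)",
                         call. = FALSE)
  tree <- truth$tree
  b <- tree$branches
  t0 <- branch_start_times(tree)
  t1 <- t0 + b$n_mut[match(names(t0), b$key)]
  fix_time <- runif(nrow(reg), config$gastrulation_window[1],
                    config$gastrulation_window[2])
  names(fix_time) <- reg$source_id
  state <- matrix(NA_character_, nrow(b), nrow(reg),
                  dimnames = list(b$key, reg$source_id))
  ord <- order(t0[b$key])  # parents before children
  for (s in seq_len(nrow(reg))) {
    p_open <- reg$p_open[s]
    p <- c(open = p_open, heterozygous = 0.15 * (1 - p_open),
           closed = 0.85 * (1 - p_open))
    fixed <- stats::setNames(rep(FALSE, nrow(b)), b$key)
    for (i in ord) {
      k <- b$key[i]
      par <- b$parent[i]
      if (t1[k] < fix_time[s] && !b$terminal[i]) {
        state[k, s] <- "open"  # pre-fixation: globally demethylated
      } else if (!is.na(par) && fixed[par]) {
        state[k, s] <- state[par, s]  # inherited after fixation
        fixed[k] <- TRUE
      } else {
        state[k, s] <- sample(names(p), 1, prob = p)  # fixed on this branch
        fixed[k] <- TRUE
      }
    }
  }
  clone_state <- state[match(vapply(tree$samples, sample_key, character(1)),
                             rownames(state)), , drop = FALSE]
  rownames(clone_state) <- tree$samples
  truth$epigenotype <- list(fix_time = fix_time, state = state,
                            clone_state = clone_state)
  truth
}

#' Simulate soL1R events on the branches of a lineage tree
#'
#' Per branch, the event count is Poisson(stage rate x branch EPM / 1000),
#' with branch EPM the truth count of endogenous mutations. Each event draws
#' a source by activity weight among sources the individual carries and
#' whose promoter epigenotype is not closed in that lineage, a class
#' (solo/partnered/orphan), mechanism flags, poly-A and TSD lengths, a
#' transduced downstream segment for transduction classes, and a target site
#' biased across replication-timing bins by `target_bin_weights`.
#'
#' @param truth a `sim_truth` from [simulate_lineage()].
#' @param registry optional pre-simulated registry (default: simulated here).
#' @param zygosity optional named allele counts per source for this
#'   individual (default: drawn from `paf_truth`).
#' @param seed optional integer seed.
#' @return the truth with `registry`, `zygosity`, `epigenotype` and `events`
#'   attached; `events` has one row per event with truth fields including
#'   `branch`, `source_id`, `class`, `twin_priming`, `foldback`,
#'   `polyA_len`, `tsd_len`, `td_len`, `chrom`, `target_pos`, `strand`.
#' @export
simulate_sol1r <- function(truth, registry = NULL, zygosity = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- truth$config
  if (is.null(registry)) registry <- simulate_registry(config)
  truth$registry <- registry
  if (is.null(zygosity)) {
    q <- 1 - sqrt(pmax(0, 1 - registry$paf_truth))  # carrier prob -> allele freq
    zygosity <- stats::setNames(stats::rbinom(nrow(registry), 2, q),
                                registry$source_id)
  }
  truth$zygosity <- zygosity
  truth <- simulate_epigenotypes(truth)

  rates <- config$sol1r_rate_by_stage
  b <- truth$tree$branches
  missing_stage <- setdiff(unique(b$stage), names(rates))
  if (length(missing_stage)) {
    stop(sprintf("no soL1R rate configured for stage(s): %s",
                 paste(missing_stage, collapse = ", ")), call. = FALSE)
  }
  epm_branch <- vapply(b$key, function(k)
    sum(truth$mutations$endogenous[truth$mutations$branch == k]), numeric(1))

  timing <- synthetic_timing_track(config$chrom_lengths)
  weights_iv <- (timing$end - timing$start) *
    config$target_bin_weights[timing$bin + 1]

  rows <- list()
  for (i in seq_len(nrow(b))) {
    lambda <- rates[[b$stage[i]]] / 1000 * epm_branch[i]
    n <- stats::rpois(1, lambda)
    if (n == 0) next
    allowed <- zygosity[registry$source_id] > 0 &
      truth$epigenotype$state[b$key[i], ] != "closed"
    w <- registry$activity * allowed
    if (all(w == 0)) next
    src_idx <- sample.int(nrow(registry), n, replace = TRUE, prob = w)
    cls <- sample(names(config$class_weights), n, replace = TRUE,
                  prob = config$class_weights)
    iv <- sample.int(nrow(timing), n, replace = TRUE, prob = weights_iv)
    pos <- floor(runif(n, timing$start[iv], timing$end[iv])) + 1
    td_len <- ifelse(cls == "solo", 0,
                     pmax(30, round(stats::rgamma(n, shape = 2, scale = 150))))
    rows[[length(rows) + 1L]] <- data.frame(
      branch = b$key[i],
      source_id = registry$source_id[src_idx],
      class = cls,
      twin_priming = cls != "orphan" & runif(n) < config$twin_frac,
      foldback = runif(n) < config$foldback_frac,
      polyA_len = pmax(5, stats::rpois(n, 60)),
      tsd_len = pmax(2, stats::rpois(n, 15)),
      td_len = td_len,
      l1_len = ifelse(cls == "orphan", 0,
                      pmax(80, round(stats::rgamma(n, shape = 1.2, scale = 400)))),
      chrom = timing$chrom[iv],
      target_pos = pos,
      strand = sample(c("+", "-"), n, TRUE),
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, rows)
  if (is.null(events)) {
    events <- data.frame(branch = character(0), source_id = character(0),
                         class = character(0), twin_priming = logical(0),
                         foldback = logical(0), polyA_len = numeric(0),
                         tsd_len = numeric(0), td_len = numeric(0),
                         l1_len = numeric(0), chrom = character(0),
                         target_pos = numeric(0), strand = character(0))
  }
  events$event_id <- if (nrow(events)) sprintf("e%04d", seq_len(nrow(events))) else character(0)
  rownames(events) <- NULL
  truth$events <- events
  truth
}

#' Simulate observed call tables from a simulated truth
#'
#' Produces the observation layer the pipeline consumes, with read-sampling
#' noise: per-clone per-mutation depth ~ Poisson(mean depth) and variant
#' reads ~ Binomial(depth, 0.5) for carried heterozygous mutations
#' (zero-depth entries are emitted, never dropped); per-clone insertion
#' calls with supporting/reference read-pair counts consistent with a fully
#' clonal cell fraction and breakpoint-anatomy mappings reflecting class and
#' mechanism; per-CpG methylation counts Binomial around the clone's
#' epigenotype level; and a population presence panel with evidence
#' fractions concentrated near 0.5 for carriers and near 0 otherwise.
#'
#' @param truth a `sim_truth` from [simulate_sol1r()].
#' @param seed optional integer seed.
#' @return list of class `sim_observation`: `vaf` and `depth`
#'   (mutation x clone matrices), `mutation_info` (observable mutation
#'   metadata: id, type, channel, coordinates), `insertions` (per-clone call
#'   table), `cpg` (per-CpG methylation counts), `panel` (individuals x
#'   sources evidence fractions), `blood` (branch-key table of bulk-blood
#'   detection of shared mutations).
#' @export
simulate_observations <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- truth$config
  tree <- truth$tree
  mut <- truth$mutations
  clones <- tree$samples
  n_mut <- nrow(mut)

  carrier <- vapply(clones, function(cl) {
    keys <- sample_path(tree, cl)
    mut$branch %in% keys
  }, logical(n_mut))
  depth <- matrix(stats::rpois(n_mut * length(clones), config$mean_depth),
                  n_mut, length(clones),
                  dimnames = list(mut$mut_id, clones))
  var_reads <- matrix(0L, n_mut, length(clones),
                      dimnames = list(mut$mut_id, clones))
  var_reads[carrier] <- stats::rbinom(sum(carrier), depth[carrier], 0.5)
  vaf <- ifelse(depth > 0, var_reads / depth, NA_real_)

  mutation_info <- mut[, c("mut_id", "type", "channel", "chrom", "pos")]

  # insertion calls: one row per event per carrying clone
  ev <- truth$events
  ins_rows <- list()
  for (i in seq_len(nrow(ev))) {
    carriers <- key_samples(ev$branch[i])
    for (cl in carriers) {
      d <- config$mean_depth
      s <- stats::rpois(1, d)            # cell fraction 1 in the clone
      r <- stats::rpois(1, d / 2)
      m <- insertion_mappings(ev[i, ], truth$registry)
      ins_rows[[length(ins_rows) + 1L]] <- cbind(
        data.frame(clone_id = cl, event_id = ev$event_id[i],
                   chrom = ev$chrom[i], target_pos = ev$target_pos[i],
                   strand = ev$strand[i], polyA_len = ev$polyA_len[i],
                   tsd_len = ev$tsd_len[i],
                   supporting_pairs = s, reference_pairs = r,
                   stringsAsFactors = FALSE),
        m)
    }
  }
  insertions <- do.call(rbind, ins_rows)
  if (is.null(insertions)) {
    insertions <- data.frame(clone_id = character(0), event_id = character(0))
  }
  rownames(insertions) <- NULL

  cpg <- simulate_methylation(truth)

  # population panel
  reg <- truth$registry
  panel <- matrix(NA_real_, config$panel_size, nrow(reg),
                  dimnames = list(sprintf("I%03d", seq_len(config$panel_size)),
                                  reg$source_id))
  for (s in seq_len(nrow(reg))) {
    carrier_i <- runif(config$panel_size) < reg$paf_truth[s]
    panel[, s] <- ifelse(carrier_i,
                         stats::rbeta(config$panel_size, 8, 8),
                         stats::rbeta(config$panel_size, 1, 30))
  }

  shared <- tree$branches[!tree$branches$terminal, , drop = FALSE]
  blood <- data.frame(branch = shared$key,
                      detected = shared$stage == "pregastrulation",
                      stringsAsFactors = FALSE)

  structure(list(vaf = vaf, depth = depth, mutation_info = mutation_info,
                 insertions = insertions, cpg = cpg, panel = panel,
                 blood = blood),
            class = "sim_observation")
}

# Breakpoint-anatomy mappings for one simulated event, on the observation
# side: L1-consensus segments for solo/partnered inserts, the downstream
# unique segment for transductions, a flank foldback mapping when present.
insertion_mappings <- function(event, registry) {
  src <- registry[registry$source_id == event$source_id, ]
  na_map <- data.frame(contig = NA_character_, start = NA_real_,
                       end = NA_real_, strand = NA_character_)
  l1_map <- function(len, inverted) {
    start <- 6019 - len + 1
    data.frame(contig = "L1", start = start, end = 6019,
               strand = if (inverted) "-" else "+")
  }
  td_map <- function() {
    offset <- floor(runif(1, 0, 5000))
    if (src$strand == "+") {
      data.frame(contig = src$chrom, start = src$end + offset + 1,
                 end = src$end + offset + event$td_len, strand = "+")
    } else {
      data.frame(contig = src$chrom, start = src$start - offset - event$td_len,
                 end = src$start - offset - 1, strand = "-")
    }
  }
  if (event$class == "solo") {
    m5 <- l1_map(event$l1_len, event$twin_priming)
    m3 <- l1_map(round(event$l1_len / 2), FALSE)
  } else if (event$class == "partnered") {
    m5 <- l1_map(event$l1_len, event$twin_priming)
    m3 <- td_map()
  } else {
    m5 <- na_map
    m3 <- td_map()
  }
  extra <- 0
  flank <- data.frame(flank5_contig = NA_character_, flank5_start = NA_real_,
                      flank5_end = NA_real_, flank5_strand = NA_character_)
  if (isTRUE(event$foldback)) {
    dup_len <- round(runif(1, 20, 120))
    extra <- round(runif(1, 52, 220))
    flank <- data.frame(flank5_contig = event$chrom,
                        flank5_start = event$target_pos - dup_len,
                        flank5_end = event$target_pos - 1,
                        flank5_strand = if (event$strand == "+") "-" else "+")
  }
  seg_len <- function(m) if (is.na(m$start)) 0 else m$end - m$start + 1
  insert_len <- seg_len(m5) + seg_len(m3) + event$polyA_len +
    (if (isTRUE(event$foldback)) flank$flank5_end - flank$flank5_start + 1 else 0) +
    extra
  cbind(data.frame(insert5_contig = m5$contig, insert5_start = m5$start,
                   insert5_end = m5$end, insert5_strand = m5$strand,
                   insert3_contig = m3$contig, insert3_start = m3$start,
                   insert3_end = m3$end, insert3_strand = m3$strand,
                   insert_len = insert_len, stringsAsFactors = FALSE),
        flank)
}

# Per-CpG methylation counts around each carried source's promoter.
simulate_methylation <- function(truth) {
  config <- truth$config
  reg <- truth$registry
  clones <- truth$tree$samples
  state <- truth$epigenotype$clone_state
  promoter_pos <- round(seq(10, 245, length.out = config$n_cpg))
  flank_pos <- c(seq(-600, -60, by = 60), seq(300, 600, by = 60))
  rows <- list()
  for (s in seq_len(nrow(reg))) {
    if (truth$zygosity[reg$source_id[s]] == 0) next
    for (cl in clones) {
      st <- state[cl, reg$source_id[s]]
      lev <- config$epi_levels[[st]]
      rel <- c(promoter_pos, flank_pos)
      level <- c(rep(lev, length(promoter_pos)),
                 rep(0.85, length(flank_pos)))
      cov <- stats::rpois(length(rel), config$meth_depth)
      meth <- stats::rbinom(length(rel), cov, level)
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = cl, source_id = reg$source_id[s], rel_pos = rel,
        meth = meth, unmeth = cov - meth, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(clone_id = character(0), source_id = character(0),
                      rel_pos = numeric(0), meth = integer(0),
                      unmeth = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Simulate one individual end to end
#'
#' Convenience wrapper chaining [simulate_lineage()], [simulate_sol1r()] and
#' [simulate_observations()] under a single seed.
#'
#' @param config a `sim_config`.
#' @param seed integer seed.
#' @param registry optional shared registry (cohort simulations).
#' @return list with `truth` and `obs`.
#' @export
simulate_individual <- function(config, seed = config$seed, registry = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_lineage(config, seed = NULL)
  truth <- simulate_sol1r(truth, registry = registry)
  obs <- simulate_observations(truth)
  list(truth = truth, obs = obs)
}
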