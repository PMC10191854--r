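# End-to-end pipeline over synthetic (or pre-loaded) data: simulate ->
# validate/classify calls -> phylogeny -> staging and rates -> sources ->
# methylation -> enrichment, collected into one structured report.

#' Run the full analysis pipeline on simulated data
#'
#' Executes the analysis chain for one simulated individual and collects a
#' structured report. Every applied threshold is echoed in the report's
#' `thresholds` section; stage sections can be restricted with `stages`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the simulation.
#' @param stages subset of c("calls", "phylogeny", "rates", "sources",
#'   "methylation", "enrichment") to run (simulation always runs).
#' @param out_dir optional directory: writes `report.json`, the event table,
#'   the newick tree and the promoter score matrix.
#' @return list of class `l1_report` with sections `config`, `thresholds`,
#'   `simulation`, and one per executed stage.
#' @export
run_pipeline <- function(config = sim_config(), seed = config$seed,
                         stages = c("calls", "phylogeny", "rates", "sources",
                                    "methylation", "enrichment"),
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim <- simulate_individual(config, seed = seed)
  truth <- sim$truth; obs <- sim$obs
  report <- list(
    config = unclass(config),
    seed = seed,
    thresholds = list(
      panel_vaf_max = 0.01, clip_prop_max = 0.70, variant_mismatch_max = 3,
      min_depth_all_samples = 5, min_max_vaf = 0.25, genotype_vaf = 0.1,
      insertion_support_frac = 0.10, transduction_window_bp = 15000,
      presence_fraction = 0.15, cpg_boundaries = c(0.25, 0.75),
      epigenotype_cutoffs = c(2.5, 7.5), promoter_window = c(1, 250)),
    simulation = list(
      n_clones = config$n_clones,
      n_mutations = nrow(truth$mutations),
      n_events = nrow(truth$events))
  )

  events <- NULL
  if ("calls" %in% stages) {
    ins <- validate_insertion(obs$insertions)
    ins <- classify_insertion(ins, truth$registry)
    ins <- annotate_mechanism(ins)
    events <- ins[ins$valid & !duplicated(ins$event_id), , drop = FALSE]
    cls <- table(factor(events$class,
                        c("solo", "partnered", "orphan", "unresolved")))
    report$calls <- list(
      n_calls = nrow(ins), n_events = nrow(events),
      class_counts = as.list(cls),
      class_pct = as.list(round(100 * cls / max(1, sum(cls)), 1)),
      twin_priming_pct = round(100 * mean(events$twin_priming), 1),
      mean_vaf = mean(insertion_vaf(events$supporting_pairs,
                                    events$reference_pairs), na.rm = TRUE))
  }

  tree <- NULL
  if ("phylogeny" %in% stages) {
    gm <- build_genotype_matrix(obs$vaf, obs$depth)
    groups <- group_mutations(gm)
    tree <- reconstruct_tree(groups)
    report$phylogeny <- list(
      n_retained = nrow(gm$genotype), dropped = as.list(gm$dropped),
      n_groups = nrow(groups), tree_length = tree_length(tree),
      n_conflict_groups = nrow(tree$discarded),
      newick = to_newick(tree))
    report$phylogeny$gm <- gm
  }

  if ("rates" %in% stages && !is.null(tree)) {
    blood <- stats::setNames(obs$blood$detected, obs$blood$branch)
    tree <- assign_stages(tree, blood_detected = blood)
    gm <- report$phylogeny$gm
    mut_key <- apply(gm$genotype, 1L, function(row)
      sample_key(colnames(gm$genotype)[row > 0]))
    stage_of <- stats::setNames(tree$branches$stage, tree$branches$key)
    mut_stage <- stage_of[mut_key]
    info <- obs$mutation_info[match(rownames(gm$genotype),
                                    obs$mutation_info$mut_id), ]
    sigs <- synthetic_signatures()
    stage_names <- c("pregastrulation", "postgastrulation", "ageing")
    epm <- stats::setNames(numeric(length(stage_names)), stage_names)
    for (st in stage_names) {
      sel <- !is.na(mut_stage) & mut_stage == st
      snv_spec <- tabulate(info$channel[sel & info$type == "SNV"], 96)
      id_spec <- tabulate(info$channel[sel & info$type == "indel"], 12)
      exp_snv <- fit_signature_exposures(snv_spec, sigs$snv)$exposures
      exp_id <- fit_signature_exposures(id_spec, sigs$indel)$exposures
      epm[st] <- count_epm(c(exp_snv, exp_id))
    }
    ev_stage <- event_stages(events, obs$insertions, tree)
    rates <- lapply(stage_names, function(st) {
      if (epm[st] > 0) sol1r_rate(sum(ev_stage == st, na.rm = TRUE), epm[st])
      else NULL
    })
    names(rates) <- stage_names
    p_cmp <- if (epm["postgastrulation"] > 0 && epm["ageing"] > 0) {
      compare_rates(sum(ev_stage == "postgastrulation", na.rm = TRUE),
                    epm[["postgastrulation"]],
                    sum(ev_stage == "ageing", na.rm = TRUE), epm[["ageing"]])
    } else NA_real_
    report$rates <- list(
      epm = as.list(epm), rates = rates,
      unassigned_mutations = sum(is.na(mut_stage)),
      unassigned_events = sum(is.na(ev_stage)),
      p_post_vs_ageing = p_cmp)
    report$rates$tree <- tree
  }

  if ("sources" %in% stages && !is.null(events)) {
    td <- events[events$class %in% c("partnered", "orphan") &
                   !is.na(events$source_id), , drop = FALSE]
    td_counts <- table(factor(td$source_id, truth$registry$source_id))
    epm_total <- sum(truth$mutations$endogenous)
    tpam <- vapply(truth$registry$source_id, function(s)
      compute_tpam(td_counts[[s]], truth$zygosity[[s]], epm_total),
      numeric(1))
    paf <- compute_paf(obs$panel)
    active <- !is.na(tpam) & tpam > 0
    report$sources <- list(
      n_transductions = nrow(td),
      tpam = as.list(tpam[active]),
      paf = as.list(round(paf, 1)),
      tpam_paf_cor = if (sum(active) >= 3)
        stats::cor(tpam[active], paf[names(tpam)[active]],
                   method = "spearman") else NA_real_)
  }

  if ("methylation" %in% stages) {
    scores <- promoter_score_matrix(obs$cpg)
    conc_tree <- if (!is.null(report$rates$tree)) report$rates$tree
                 else if (!is.null(tree)) tree else truth$tree
    conc <- tryCatch(
      concordance_vs_branching(conc_tree, scores, top_k = 30),
      error = function(e) NULL)
    open_frac <- mean(call_epigenotype(scores) != "closed", na.rm = TRUE)
    report$methylation <- list(
      n_scored = sum(!is.na(scores)),
      demethylated_frac = round(open_frac, 3),
      concordance = if (!is.null(conc))
        conc$by_stratum[, c("stratum", "n_pairs", "concordance")] else NULL,
      ks_statistic = if (!is.null(conc) && !is.null(conc$ks))
        conc$ks$statistic else NA_real_)
  }

  if ("enrichment" %in% stages && !is.null(events)) {
    track <- synthetic_timing_track(config$chrom_lengths)
    site_tab <- data.frame(chrom = events$chrom, pos = events$target_pos)
    enr <- enrichment_scores(site_tab, track)
    win <- window_insertion_rate(site_tab, config$chrom_lengths)
    report$enrichment <- list(
      replication_timing = enr,
      max_window_count = max(win$count),
      n_windows = nrow(win))
  }

  report$phylogeny$gm <- NULL
  class(report) <- "l1_report"
  if (!is.null(out_dir)) write_report(report, tree, events, out_dir)
  report
}

# Stage of each deduplicated event, via the carrier-set key of its clones.
event_stages <- function(events, insertions, tree) {
  if (is.null(events) || !nrow(events)) return(character(0))
  stage_of <- stats::setNames(tree$branches$stage, tree$branches$key)
  vapply(events$event_id, function(id) {
    carriers <- unique(insertions$clone_id[insertions$event_id == id])
    k <- sample_key(carriers)
    if (k %in% names(stage_of)) stage_of[[k]] else NA_character_
  }, character(1))
}

write_report <- function(report, tree, events, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clean <- report
  clean$rates$tree <- NULL
  jsonlite::write_json(clean, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  if (!is.null(tree)) write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
  if (!is.null(events)) {
    utils::write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.l1_report <- function(x, ...) {
  cat("l1mosaic pipeline report\n")
  cat(sprintf("  clones: %d, mutations: %d, soL1R events: %d\n",
              x$simulation$n_clones, x$simulation$n_mutations,
              x$simulation$n_events))
  if (!is.null(x$calls)) {
    cat(sprintf("  classes (%%): solo %.1f, partnered %.1f, orphan %.1f\n",
                x$calls$class_pct$solo, x$calls$class_pct$partnered,
                x$calls$class_pct$orphan))
  }
  if (!is.null(x$rates)) {
    for (st in names(x$rates$rates)) {
      r <- x$rates$rates[[st]]
      if (!is.null(r)) {
        cat(sprintf("  %s: %d events / %d EPM = %.2f per 1,000 EPMs (95%% CI %.2f-%.2f)\n",
                    st, r$events, r$epm, r$rate, r$ci_lower, r$ci_upper))
      }
    }
  }
  invisible(x)
}
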