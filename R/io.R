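# Shared table schemas, validated TSV readers/writers, newick and YAML IO.
# External tables use 1-based inclusive coordinates (VCF convention);
# interval tracks use 0-based half-open coordinates (BED convention).

l1mosaic_schemas <- list(
  events = c("clone_id", "chrom", "target_pos", "strand", "polyA_len",
             "tsd_len", "supporting_pairs", "reference_pairs"),
  variants = c("chrom", "pos", "ref", "alt"),
  methylation = c("clone_id", "source_id", "rel_pos", "meth", "unmeth"),
  registry = c("source_id", "chrom", "start", "end", "strand"),
  panel = c("individual", "source_id", "evidence_fraction"),
  track = c("chrom", "start", "end", "signal")
)

#' Read a tab-separated table against a registered schema
#'
#' @param path file path.
#' @param schema one of "events", "variants", "methylation", "registry",
#'   "panel", "track".
#' @return validated data.frame. Missing required columns are an error;
#'   unknown extra columns produce a warning and are kept.
#' @export
read_l1_table <- function(path, schema = names(l1mosaic_schemas)) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- l1mosaic_schemas[[schema]]
  require_columns(df, required, sprintf("%s table '%s'", schema, path))
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("%s table has unrecognized column(s): %s",
                    schema, paste(extra, collapse = ", ")))
  }
  df
}

#' Write a table as TSV, verifying its schema
#'
#' @param df data.frame to write.
#' @param path destination path.
#' @param schema registered schema name (see [read_l1_table()]).
#' @return `path`, invisibly.
#' @export
write_l1_table <- function(df, path, schema = names(l1mosaic_schemas)) {
  schema <- match.arg(schema)
  require_columns(df, l1mosaic_schemas[[schema]], sprintf("%s table", schema))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a lineage tree as newick
#' @param tree a `lineage_tree`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}

#' Read a newick tree as an ape phylo object
#' @param path newick file.
#' @return an ape `phylo`.
#' @export
read_tree_newick <- function(path) {
  ape::read.tree(path)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file.
#' @return for the reader, a `sim_config` built from the stored fields over
#'   the defaults of [sim_config()].
#' @export
read_sim_config <- function(path) {
  fields <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown config field(s): %s",
                    paste(unknown, collapse = ", ")))
    fields <- fields[intersect(names(fields), known)]
  }
  for (nm in c("sol1r_rate_by_stage", "class_weights", "epi_levels",
               "chrom_lengths")) {
    if (!is.null(fields[[nm]])) fields[[nm]] <- unlist(fields[[nm]])
  }
  do.call(sim_config, fields)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  fields <- unclass(config)
  # named atomic vectors must become maps, or YAML drops the names
  for (nm in names(fields)) {
    if (!is.null(names(fields[[nm]]))) fields[[nm]] <- as.list(fields[[nm]])
  }
  yaml::write_yaml(fields, path)
  invisible(path)
}
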