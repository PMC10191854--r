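# Reconstruction of the rooted developmental phylogeny of clones from a
# binary genotype matrix of postzygotic mutations.

#' Build a binary genotype matrix from VAF and depth matrices
#'
#' Candidate mutations are filtered exactly as in the multi-sample genotyping
#' procedure: rows are dropped unless depth is at least `min_depth` in every
#' sample and VAF reaches at least `min_max_vaf` in at least one sample. The
#' genotype entry M_ij is 1 iff VAF_ij > `genotype_vaf` (strict inequality).
#' Rows genotyped 1 in every sample are germline and are discarded.
#'
#' @param vaf numeric matrix, mutations x samples.
#' @param depth numeric matrix, mutations x samples.
#' @param min_depth minimum depth in every sample (default 5).
#' @param min_max_vaf minimum of per-row maximum VAF (default 0.25).
#' @param genotype_vaf VAF above which an entry is genotyped 1 (default 0.1).
#' @return list of class `genotype_matrix`: `genotype` (binary matrix over
#'   retained rows), `vaf` (provenance VAF of retained rows), and `dropped`,
#'   a named count of rows removed per rule. An input that filters to zero
#'   rows yields an empty (0-row) matrix, not an error.
#' @export
build_genotype_matrix <- function(vaf, depth, min_depth = 5,
                                  min_max_vaf = 0.25, genotype_vaf = 0.1) {
  vaf <- as.matrix(vaf); depth <- as.matrix(depth)
  if (!all(dim(vaf) == dim(depth))) {
    stop("`vaf` and `depth` must have identical dimensions", call. = FALSE)
  }
  cov_ok <- apply(depth, 1L, function(d) all(!is.na(d) & d >= min_depth))
  vaf_ok <- apply(vaf, 1L, function(v) any(v >= min_max_vaf, na.rm = TRUE))
  keep1 <- cov_ok & vaf_ok
  gt <- (vaf > genotype_vaf) * 1L
  gt[is.na(gt)] <- 0L
  germline <- rowSums(gt) == ncol(gt)
  keep <- keep1 & !germline
  structure(list(
    genotype = gt[keep, , drop = FALSE],
    vaf = vaf[keep, , drop = FALSE],
    dropped = c(coverage = sum(!cov_ok),
                max_vaf = sum(cov_ok & !vaf_ok),
                germline = sum(keep1 & germline))
  ), class = "genotype_matrix")
}

#' Group mutations by the exact set of samples carrying them
#'
#' Mutations are grouped by the identity of the carrying sample set; group B
#' is subordinate to group A when B's samples are a proper subset of A's.
#'
#' @param gm a `genotype_matrix` (see [build_genotype_matrix()]) or a plain
#'   binary matrix with sample names as columns.
#' @return data.frame of class `mutation_groups` with columns `key` (sorted
#'   "+"-joined sample ids), `size` (mutation count) and `n_samples`, ordered
#'   by decreasing size then key.
#' @export
group_mutations <- function(gm) {
  m <- if (inherits(gm, "genotype_matrix")) gm$genotype else as.matrix(gm)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  if (!nrow(m)) {
    out <- data.frame(key = character(0), size = integer(0),
                      n_samples = integer(0), stringsAsFactors = FALSE)
  } else {
    keys <- apply(m, 1L, function(row) sample_key(colnames(m)[row > 0]))
    tab <- table(keys)
    out <- data.frame(key = names(tab), size = as.integer(tab),
                      stringsAsFactors = FALSE)
    out$n_samples <- lengths(lapply(out$key, key_samples))
    out <- out[order(-out$size, out$key), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "samples") <- colnames(m)
  class(out) <- c("mutation_groups", class(out))
  out
}

#' Subset partial order between two mutation groups
#'
#' @param key_a,key_b group keys as produced by [sample_key()].
#' @return one of "subordinate" (A strictly inside B), "superior" (A strictly
#'   contains B), "equal", "disjoint", or "conflict" (overlapping,
#'   non-nested).
#' @export
group_relation <- function(key_a, key_b) {
  a <- key_samples(key_a); b <- key_samples(key_b)
  inter <- length(intersect(a, b))
  if (inter == 0L) return("disjoint")
  if (inter == length(a) && inter == length(b)) return("equal")
  if (inter == length(a)) return("subordinate")
  if (inter == length(b)) return("superior")
  "conflict"
}

#' Reconstruct the rooted clone phylogeny from mutation groups
#'
#' Accepts mutation groups greedily in order of decreasing size (ties broken
#' lexicographically by key); a group whose sample set overlaps an accepted
#' group without nesting is in conflict, its mutations are discarded from the
#' tree and logged. The accepted groups form a laminar family that defines a
#' unique rooted tree: each sample attaches at a terminal node, each branch
#' carries one mutation group, and branch length is the group's mutation
#' count. Samples without a private mutation group get a zero-length terminal
#' branch.
#'
#' @param groups a `mutation_groups` object (see [group_mutations()]).
#' @param samples character vector of all sample ids (defaults to the samples
#'   recorded on `groups`).
#' @return an object of class `lineage_tree`: list with `samples`,
#'   `branches` (data.frame: `key`, `parent` key or NA, `n_mut`, `terminal`,
#'   `stage` initialized NA) and `discarded` (conflicting groups).
#' @export
reconstruct_tree <- function(groups, samples = attr(groups, "samples")) {
  if (is.null(samples)) stop("sample ids are required", call. = FALSE)
  samples <- sort(unique(samples))
  accepted <- character(0)
  discard <- groups[0, , drop = FALSE]
  sets <- lapply(groups$key, key_samples)
  acc_sets <- list()
  for (i in seq_len(nrow(groups))) {
    s <- sets[[i]]
    ok <- all(vapply(acc_sets, function(a) {
      inter <- length(intersect(a, s))
      inter == 0L || inter == length(a) || inter == length(s)
    }, logical(1)))
    if (ok) {
      accepted <- c(accepted, groups$key[i])
      acc_sets <- c(acc_sets, list(s))
    } else {
      discard <- rbind(discard, groups[i, , drop = FALSE])
    }
  }
  sizes <- stats::setNames(groups$size, groups$key)[accepted]
  # ensure every sample has a terminal (singleton) branch
  singles <- vapply(samples, function(s) sample_key(s), character(1))
  add <- setdiff(singles, accepted)
  keys <- c(accepted, add)
  n_mut <- c(sizes, stats::setNames(rep(0L, length(add)), add))
  set_list <- lapply(keys, key_samples)
  card <- lengths(set_list)
  # parent of a set: smallest accepted set strictly containing it
  parent <- vapply(seq_along(keys), function(i) {
    sup <- which(card > card[i] &
                   vapply(set_list, function(a)
                     all(set_list[[i]] %in% a), logical(1)))
    if (!length(sup)) return(NA_character_)
    keys[sup[which.min(card[sup])]]
  }, character(1))
  branches <- data.frame(
    key = keys, parent = parent, n_mut = as.numeric(n_mut[keys]),
    terminal = card == 1L, stage = NA_character_,
    stringsAsFactors = FALSE)
  branches <- branches[order(-lengths(lapply(branches$key, key_samples)),
                             branches$key), , drop = FALSE]
  rownames(branches) <- NULL
  structure(list(samples = samples, branches = branches,
                 discarded = discard),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d samples, %d branches, %.0f mutations on tree",
              length(x$samples), nrow(x$branches), sum(x$branches$n_mut)))
  if (nrow(x$discarded)) {
    cat(sprintf(" (%d mutations in %d conflicting groups discarded)",
                sum(x$discarded$size), nrow(x$discarded)))
  }
  cat("\n")
  invisible(x)
}

#' Total branch length of a lineage tree
#' @param tree a `lineage_tree`.
#' @return numeric: sum of branch mutation counts.
#' @export
tree_length <- function(tree) sum(tree$branches$n_mut)

#' Root-to-leaf branch path for one sample
#' @param tree a `lineage_tree`.
#' @param sample sample id.
#' @return character vector of branch keys from the earliest branch down to
#'   the terminal branch.
#' @export
sample_path <- function(tree, sample) {
  b <- tree$branches
  on_path <- vapply(b$key, function(k) sample %in% key_samples(k), logical(1))
  keys <- b$key[on_path]
  keys[order(-lengths(lapply(keys, key_samples)))]
}

#' Molecular time of the most recent common ancestor of every clone pair
#'
#' Molecular time is measured in mutations: the MRCA time of a pair is the
#' number of mutations on the branches shared by both clones (their common
#' root-to-MRCA path).
#'
#' @param tree a `lineage_tree`.
#' @return symmetric numeric matrix, clones x clones, diagonal NA.
#' @export
pair_mrca_time <- function(tree) {
  m <- length(tree$samples)
  b <- tree$branches
  member <- vapply(b$key, function(k) tree$samples %in% key_samples(k),
                   logical(m))
  member <- matrix(member, nrow = m,
                   dimnames = list(tree$samples, b$key))
  out <- matrix(NA_real_, m, m, dimnames = list(tree$samples, tree$samples))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) {
      shared <- member[i, ] & member[j, ]
      out[i, j] <- sum(b$n_mut[shared])
    }
  }
  out
}

#' Serialize a lineage tree to a newick string
#'
#' Branch lengths are mutation counts. The virtual root joins the top-level
#' branches with zero length.
#'
#' @param tree a `lineage_tree`.
#' @return single newick string terminated by ";".
#' @export
to_newick <- function(tree) {
  b <- tree$branches
  render <- function(key) {
    kids <- b$key[!is.na(b$parent) & b$parent == key]
    len <- b$n_mut[b$key == key]
    if (!length(kids)) {
      sprintf("%s:%g", key_samples(key), len)
    } else {
      sprintf("(%s):%g", paste(vapply(kids, render, character(1)),
                               collapse = ","), len)
    }
  }
  top <- b$key[is.na(b$parent)]
  inner <- paste(vapply(top, render, character(1)), collapse = ",")
  sprintf("(%s);", inner)
}

#' Convert a lineage tree to an ape "phylo" object
#' @param tree a `lineage_tree`.
#' @return an [ape::read.tree()] phylo object with mutation-count branch
#'   lengths.
#' @export
as_phylo <- function(tree) {
  txt <- to_newick(tree)
  ape::read.tree(text = txt)
}
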