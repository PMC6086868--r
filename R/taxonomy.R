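#' Default rank ladder used for rank-wise walks
#'
#' The ordered list of named ranks, most inclusive first. Ranks not on this
#' ladder (NCBI "no rank" clades, strain-level labels, ...) are transparent
#' during rank-wise traversal: they never stall a walk, they are simply
#' skipped. The ladder is configuration, not a constant — pass a modified
#' vector wherever a `ranks` argument is accepted.
#'
#' @return Character vector of rank labels, superkingdom first.
#' @export
default_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Load a taxonomy from NCBI-style dump files
#'
#' Reads the pipe-delimited `nodes.dmp` / `names.dmp` dialect
#' (`taxid | parent | rank |` and `taxid | name | unique | class |`; both
#' `\t|\t` and bare `|` separators are accepted). Only scientific names are
#' kept from the names file. The root node is its own parent.
#'
#' @param nodes_path Path to the nodes file.
#' @param names_path Path to the names file.
#' @return A `taxonomy` object: list with `nodes` (tibble: taxid, parent,
#'   rank, name), `parent` (named integer lookup), `rank`, `name` (named
#'   character lookups) and `root` (integer taxid).
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  split_dmp <- function(lines) {
    lines <- sub("\\t?\\|\\s*$", "", lines)
    strsplit(lines, "\\s*\\t?\\|\\t?\\s*")
  }
  nl <- readLines(nodes_path)
  nl <- nl[nzchar(trimws(nl))]
  fields <- split_dmp(nl)
  taxid <- as.integer(vapply(fields, `[`, "", 1L))
  parent <- as.integer(vapply(fields, `[`, "", 2L))
  rank <- trimws(vapply(fields, function(f) if (length(f) >= 3) f[3] else "no rank", ""))
  rank[!nzchar(rank)] <- "no rank"
  if (anyNA(taxid) || anyNA(parent)) {
    stop("malformed nodes file: non-integer taxid or parent", call. = FALSE)
  }
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid in nodes file: ", taxid[duplicated(taxid)][1], call. = FALSE)
  }

  nm <- readLines(names_path)
  nm <- nm[nzchar(trimws(nm))]
  nf <- split_dmp(nm)
  n_taxid <- as.integer(vapply(nf, `[`, "", 1L))
  n_name <- trimws(vapply(nf, `[`, "", 2L))
  n_class <- trimws(vapply(nf, function(f) if (length(f) >= 4) f[4] else "scientific name", ""))
  keep <- n_class == "scientific name" | !nzchar(n_class)
  name_lookup <- stats::setNames(n_name[keep], n_taxid[keep])

  new_taxonomy(taxid, parent, rank,
               name = unname(name_lookup[as.character(taxid)]))
}

#' Build a taxonomy from vectors
#'
#' Programmatic constructor used by the synthetic-world generator and tests;
#' validates the same invariants as [load_taxonomy()]: every parent must
#' exist, exactly one root (its own parent), no cycles.
#'
#' @param taxid,parent Integer vectors of equal length.
#' @param rank Character vector of rank labels ("no rank" where unranked).
#' @param name Optional character vector of scientific names.
#' @return A `taxonomy` object.
#' @export
new_taxonomy <- function(taxid, parent, rank, name = NULL) {
  taxid <- as.integer(taxid)
  parent <- as.integer(parent)
  if (is.null(name)) name <- paste0("taxon_", taxid)
  name[is.na(name)] <- paste0("taxon_", taxid[is.na(name)])
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent) > 0) {
    stop("orphan parent ", missing_parent[1], ": referenced but not defined",
         call. = FALSE)
  }
  root <- taxid[taxid == parent]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (self-parent node), found ",
         length(root), call. = FALSE)
  }
  parent_lk <- stats::setNames(parent, taxid)
  # cycle check: walk each node to root, path length bounded by node count
  n <- length(taxid)
  for (t in taxid) {
    cur <- t
    steps <- 0L
    while (cur != root) {
      cur <- parent_lk[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", t, call. = FALSE)
    }
  }
  structure(
    list(
      nodes = tibble::tibble(taxid = taxid, parent = parent,
                             rank = rank, name = name),
      parent = parent_lk,
      rank = stats::setNames(rank, taxid),
      name = stats::setNames(name, taxid),
      root = root
    ),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root ", x$root, "\n", sep = "")
  ranks <- sort(table(x$nodes$rank), decreasing = TRUE)
  cat("  ranks:", paste0(names(ranks), " (", ranks, ")", collapse = ", "), "\n")
  invisible(x)
}

check_taxid <- function(tree, taxid) {
  bad <- taxid[!as.character(taxid) %in% names(tree$parent)]
  if (length(bad) > 0) stop("unknown taxid: ", bad[1], call. = FALSE)
  invisible(TRUE)
}

#' Lineage of a taxon
#'
#' @param tree A `taxonomy`.
#' @param taxid A single taxid present in the tree.
#' @return Integer vector of taxids, root first, `taxid` last.
#' @export
lineage <- function(tree, taxid) {
  check_taxid(tree, taxid)
  path <- integer(0)
  cur <- as.integer(taxid)
  while (TRUE) {
    path <- c(cur, path)
    if (cur == tree$root) break
    cur <- tree$parent[[as.character(cur)]]
  }
  path
}

#' Is one taxon a descendant of another?
#'
#' Reflexive: every taxon is its own descendant. Every taxon descends from
#' the root.
#'
#' @param tree A `taxonomy`.
#' @param child,ancestor Taxids present in the tree.
#' @return Logical scalar.
#' @export
is_descendant <- function(tree, child, ancestor) {
  check_taxid(tree, c(child, ancestor))
  ancestor <- as.integer(ancestor)
  cur <- as.integer(child)
  while (TRUE) {
    if (cur == ancestor) return(TRUE)
    if (cur == tree$root) return(FALSE)
    cur <- tree$parent[[as.character(cur)]]
  }
}

#' Lowest common ancestor of a pair of taxa
#'
#' @param tree A `taxonomy`.
#' @param a,b Taxids present in the tree.
#' @return The taxid of the deepest node lying on both lineages.
#' @export
lca_pair <- function(tree, a, b) {
  la <- lineage(tree, a)
  lb <- lineage(tree, b)
  common <- la[seq_len(min(length(la), length(lb)))] ==
    lb[seq_len(min(length(la), length(lb)))]
  la[max(which(common))]
}

#' Ancestor of a taxon at a given rank
#'
#' Walks the lineage and returns the ancestor whose rank label equals
#' `rank`, or `NA` if the lineage has no node at that rank (unranked
#' intermediate clades are transparent).
#'
#' @param tree A `taxonomy`.
#' @param taxid A taxid in the tree.
#' @param rank A single rank label.
#' @return Integer taxid or `NA_integer_`.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  lin <- lineage(tree, taxid)
  hits <- lin[tree$rank[as.character(lin)] == rank]
  if (length(hits) == 0) NA_integer_ else hits[length(hits)]
}
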