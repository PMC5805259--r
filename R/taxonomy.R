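# Rank-labelled viral taxonomy: order -> family -> genus -> species.
# Nodes form a forest; a node's parent must sit at a strictly shallower rank
# (genus may hang directly off a family when the database records no genus).

#' Sentinel label for reads or table rows without a determinate taxon
#' @export
UNDETERMINED <- "UNDETERMINED"

#' Recognised taxonomic ranks, shallow to deep
#' @export
TAXONOMY_RANKS <- c("order", "family", "genus", "species")

#' Recognised viral reference classes
#' @export
VIRAL_CLASSES <- c("prophage", "bacteriophage", "eukaryotic_virus")

.rank_depth <- function(rank) match(rank, TAXONOMY_RANKS)

#' Construct a rank-labelled viral taxonomy
#'
#' Builds the taxonomy object used throughout the pipeline: a forest of
#' nodes at ranks order/family/genus/species, plus a mapping from reference
#' subject sequences to taxonomy nodes and viral classes (prophage,
#' bacteriophage, eukaryotic virus).
#'
#' Node names use the supplementary-table conventions of oral virome
#' surveys: the literal name `"u"` marks an undetermined taxon at that rank
#' and `"n"` a taxon with no name in the source database. Lineage strings
#' render ranks as `o__`, `f__`, `g__`, `s__` prefixed labels joined by
#' semicolons, with ranks absent from a node's ancestry rendered as
#' undetermined (`g__u`).
#'
#' @param nodes data.frame with columns `taxon_id`, `name`, `rank`,
#'   `parent_id` (`NA` for roots).
#' @param subjects data.frame with columns `subject_id`, `taxon_id`,
#'   `viral_class`, mapping reference sequences to nodes.
#' @return An object of class `virome_taxonomy`.
#' @export
virome_taxonomy <- function(nodes, subjects) {
  need <- c("taxon_id", "name", "rank", "parent_id")
  if (!all(need %in% names(nodes))) {
    stop("taxonomy nodes need columns: ", paste(need, collapse = ", "))
  }
  need_s <- c("subject_id", "taxon_id", "viral_class")
  if (!all(need_s %in% names(subjects))) {
    stop("subject map needs columns: ", paste(need_s, collapse = ", "))
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == ""] <- NA_character_

  if (anyDuplicated(nodes$taxon_id)) {
    stop("duplicate taxon_id in taxonomy nodes")
  }
  bad_rank <- setdiff(unique(nodes$rank), TAXONOMY_RANKS)
  if (length(bad_rank)) {
    stop("unknown taxonomy rank(s): ", paste(bad_rank, collapse = ", "))
  }
  has_parent <- !is.na(nodes$parent_id)
  missing_parent <- setdiff(nodes$parent_id[has_parent], nodes$taxon_id)
  if (length(missing_parent)) {
    stop("parent_id not present as a node: ",
         paste(missing_parent, collapse = ", "))
  }
  if (any(has_parent & nodes$parent_id == nodes$taxon_id)) {
    stop("taxonomy structural error: node is its own parent")
  }
  # parent must be strictly shallower
  pidx <- match(nodes$parent_id, nodes$taxon_id)
  pd <- .rank_depth(nodes$rank[pidx])
  cd <- .rank_depth(nodes$rank)
  if (any(has_parent & pd >= cd, na.rm = TRUE)) {
    stop("taxonomy structural error: parent rank not shallower than child")
  }
  # acyclicity: walk each node to a root; depth bounded by number of ranks
  parent_of <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  for (id in nodes$taxon_id) {
    seen <- character(0)
    cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("taxonomy structural error: cycle at ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  bad_subj <- setdiff(subjects$taxon_id, nodes$taxon_id)
  if (length(bad_subj)) {
    stop("subject mapped to absent taxon: ", paste(bad_subj, collapse = ", "))
  }
  bad_cls <- setdiff(unique(subjects$viral_class),
                     c(VIRAL_CLASSES, "bacterial"))
  if (length(bad_cls)) {
    stop("unknown viral_class: ", paste(bad_cls, collapse = ", "))
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in subject map")
  }
  structure(
    list(nodes = nodes, subjects = subjects),
    class = "virome_taxonomy"
  )
}

#' @export
print.virome_taxonomy <- function(x, ...) {
  cat("virome_taxonomy:", nrow(x$nodes), "nodes (",
      paste(vapply(TAXONOMY_RANKS, function(r) sum(x$nodes$rank == r), 1L),
            TAXONOMY_RANKS, collapse = ", "),
      "),", nrow(x$subjects), "reference subjects\n")
  invisible(x)
}

#' Ancestor chain of a taxon, self first, root last
#'
#' @param tree a `virome_taxonomy`
#' @param taxon_id node identifier
#' @return character vector of taxon_ids from the node up to its root.
#' @export
tax_ancestors <- function(tree, taxon_id) {
  parent_of <- stats::setNames(tree$nodes$parent_id, tree$nodes$taxon_id)
  if (!taxon_id %in% names(parent_of)) {
    stop("unknown taxon_id: ", taxon_id)
  }
  out <- character(0)
  cur <- taxon_id
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- parent_of[[cur]]
  }
  out
}

#' Ancestor of a taxon at a given rank (or NA if the node is shallower)
#'
#' @inheritParams tax_ancestors
#' @param rank target rank, one of `TAXONOMY_RANKS`
#' @return taxon_id at `rank`, or `NA_character_` when the node's lineage
#'   does not reach that rank (node shallower than `rank`, or rank skipped).
#' @export
tax_ancestor_at_rank <- function(tree, taxon_id, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  chain <- tax_ancestors(tree, taxon_id)
  ranks <- tree$nodes$rank[match(chain, tree$nodes$taxon_id)]
  hit <- chain[ranks == rank]
  if (length(hit)) hit[[1]] else NA_character_
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every taxon in the set.
#' Returns `NA_character_` when the taxa share no node (disjoint trees in
#' the forest).
#'
#' @param tree a `virome_taxonomy`
#' @param taxon_ids character vector of node identifiers
#' @export
tax_lca <- function(tree, taxon_ids) {
  taxon_ids <- unique(taxon_ids)
  if (!length(taxon_ids)) return(NA_character_)
  if (length(taxon_ids) == 1L) return(taxon_ids)
  chains <- lapply(taxon_ids, function(id) tax_ancestors(tree, id))
  common <- Reduce(intersect, chains)
  if (!length(common)) return(NA_character_)
  depths <- .rank_depth(tree$nodes$rank[match(common, tree$nodes$taxon_id)])
  common[which.max(depths)]
}

#' Rank of a taxonomy node
#' @inheritParams tax_ancestors
#' @export
tax_rank <- function(tree, taxon_id) {
  r <- tree$nodes$rank[match(taxon_id, tree$nodes$taxon_id)]
  if (any(is.na(r))) stop("unknown taxon_id")
  r
}

#' Semicolon-joined, rank-prefixed lineage string
#'
#' Renders a node's lineage down to `to_rank` in the `o__X;f__Y;g__Z;s__W`
#' dialect. Ranks deeper than the node, or skipped in its ancestry, are
#' rendered undetermined (`__u`). The `UNDETERMINED` sentinel is passed
#' through unchanged.
#'
#' @inheritParams tax_ancestors
#' @param to_rank deepest rank to render (default `"species"`)
#' @export
tax_lineage <- function(tree, taxon_id, to_rank = "species") {
  to_rank <- match.arg(to_rank, TAXONOMY_RANKS)
  if (identical(taxon_id, UNDETERMINED)) return(UNDETERMINED)
  chain <- tax_ancestors(tree, taxon_id)
  idx <- match(chain, tree$nodes$taxon_id)
  ranks <- tree$nodes$rank[idx]
  names_of <- stats::setNames(tree$nodes$name[idx], ranks)
  prefixes <- c(order = "o__", family = "f__", genus = "g__",
                species = "s__")
  keep <- TAXONOMY_RANKS[seq_len(.rank_depth(to_rank))]
  parts <- vapply(keep, function(r) {
    nm <- if (r %in% names(names_of)) names_of[[r]] else "u"
    paste0(prefixes[[r]], nm)
  }, character(1))
  paste(parts, collapse = ";")
}

# viral class of a reference subject (internal)
.subject_class <- function(tree, subject_id) {
  cls <- tree$subjects$viral_class[match(subject_id, tree$subjects$subject_id)]
  if (any(is.na(cls))) {
    stop("missing viral_class annotation for subject: ",
         paste(subject_id[is.na(cls)], collapse = ", "))
  }
  cls
}

# taxon of a reference subject (internal)
.subject_taxon <- function(tree, subject_id) {
  tx <- tree$subjects$taxon_id[match(subject_id, tree$subjects$subject_id)]
  if (any(is.na(tx))) {
    stop("unknown subject_id: ",
         paste(unique(subject_id[is.na(tx)]), collapse = ", "))
  }
  tx
}
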