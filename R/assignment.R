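# Hit filtering and best-hit / lowest-common-ancestor read assignment.
#
# A read keeps the hits that pass the similarity thresholds; the retained
# hits are ranked by identity, then alignment length, then bit score. If a
# single taxon wins, the read is assigned at that (closest-to-tip) node;
# when several hits are co-optimal the read falls back to the lowest common
# ancestor of their taxa, or to UNDETERMINED when they share no ancestor.

#' Similarity thresholds for retaining alignment hits
#'
#' Defaults follow the standard virome-profiling regime: e-value strictly
#' below 1e-3, identity at least 80 percent, and an alignment spanning at
#' least 75 percent of the read length.
#'
#' @param max_evalue exclusive upper bound on the e-value.
#' @param min_identity inclusive lower bound on percent identity, in
#'   `[0, 100]`.
#' @param min_coverage inclusive lower bound on
#'   `alignment_length / query_length`, in `(0, 1]`.
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_evalue = 1e-3, min_identity = 80,
                              min_coverage = 0.75) {
  stopifnot(max_evalue > 0,
            min_identity >= 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1)
  structure(list(max_evalue = max_evalue, min_identity = min_identity,
                 min_coverage = min_coverage),
            class = "filter_thresholds")
}

#' Filter alignment hits on e-value, identity and read coverage
#'
#' Retains hits with `e_value < max_evalue`,
#' `percent_identity >= min_identity` and
#' `alignment_length / query_length >= min_coverage`. Row order is
#' preserved and the operation is idempotent.
#'
#' @param hits data.frame of hits from [read_hit_table()] (every row must
#'   carry `query_length`).
#' @param thresholds a [filter_thresholds()].
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!nrow(hits)) return(hits)
  if (anyNA(hits$query_length)) stop("filter_hits: query_length missing")
  keep <- hits$e_value < thresholds$max_evalue &
    hits$percent_identity >= thresholds$min_identity &
    hits$alignment_length / hits$query_length >= thresholds$min_coverage
  hits[keep, , drop = FALSE]
}

# Rank hits best-first: identity desc, alignment length desc, bit score
# desc. Keeps only the best hit per (query, subject) pair first.
.rank_hits <- function(hits) {
  ord <- order(-hits$percent_identity, -hits$alignment_length,
               -hits$bit_score)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$subject_id), , drop = FALSE]
}

# Co-optimal set: hits whose identity is within `tie_margin` percentage
# points of the top hit and whose alignment length is within `tie_margin`
# percent of the top hit's length. tie_margin = 0 keeps exact ties only.
.co_optimal <- function(ranked, tie_margin) {
  top <- ranked[1, ]
  keep <- ranked$percent_identity >= top$percent_identity - tie_margin &
    ranked$alignment_length >= top$alignment_length * (1 - tie_margin / 100)
  ranked[keep, , drop = FALSE]
}

#' Assign one read from its filtered hits (best hit or LCA)
#'
#' Hits are ranked by percent identity, then alignment length, then bit
#' score. The co-optimal set is every hit within `tie_margin` of the top
#' hit on both identity (percentage points) and alignment length (percent
#' of the top length); `tie_margin = 0` means exact ties. If the co-optimal
#' hits all map to one taxon the read is assigned there (closest to the
#' tip); otherwise it is assigned to the lowest common ancestor of their
#' taxa, or `UNDETERMINED` when no common ancestor exists.
#'
#' The read's viral class is the majority class over the co-optimal hits,
#' with ties broken by the top-ranked hit's class.
#'
#' @param hits filtered hits for a single query.
#' @param tree a [virome_taxonomy()].
#' @param tie_margin co-optimality margin (identity percentage points);
#'   default 0.
#' @return one-row data.frame: `query_id`, `taxon_id`, `resolution_rank`,
#'   `co_optimal_count`, `viral_class`.
#' @export
assign_read <- function(hits, tree, tie_margin = 0) {
  stopifnot(nrow(hits) >= 1, tie_margin >= 0)
  if (length(unique(hits$query_id)) != 1L) {
    stop("assign_read expects hits for a single query")
  }
  ranked <- .rank_hits(hits)
  co <- .co_optimal(ranked, tie_margin)
  taxa <- .subject_taxon(tree, co$subject_id)
  classes <- .subject_class(tree, co$subject_id)
  utaxa <- unique(taxa)
  if (length(utaxa) == 1L) {
    taxon <- utaxa
    rank <- tax_rank(tree, taxon)
  } else {
    taxon <- tax_lca(tree, utaxa)
    if (is.na(taxon)) {
      taxon <- UNDETERMINED
      rank <- NA_character_
    } else {
      rank <- tax_rank(tree, taxon)
    }
  }
  # majority class over co-optimal hits; tie -> class of top-ranked hit
  tab <- table(classes)
  winners <- names(tab)[tab == max(tab)]
  cls <- if (length(winners) == 1L) winners else classes[1]
  data.frame(query_id = hits$query_id[1], taxon_id = taxon,
             resolution_rank = rank, co_optimal_count = nrow(co),
             viral_class = cls, stringsAsFactors = FALSE)
}

#' Assign every read with viral homology; count bacterial-only reads
#'
#' Filters both hit tables, then produces exactly one assignment per
#' distinct query with at least one retained viral hit. `bacterial_hit` is
#' TRUE for the viral queries that also retain a bacterial hit (the
#' virus-and-bacteria homology pool); queries retaining only bacterial
#' hits are counted separately as bacterial reads and do not receive
#' assignments.
#'
#' @param viral_hits,bacterial_hits hit data.frames from
#'   [read_hit_table()].
#' @param tree a [virome_taxonomy()].
#' @param thresholds a [filter_thresholds()].
#' @param tie_margin co-optimality margin, see [assign_read()].
#' @param sample_id optional sample label attached to every assignment.
#' @return list with `assignments` (data.frame: `sample_id`, `query_id`,
#'   `taxon_id`, `resolution_rank`, `co_optimal_count`, `viral_class`,
#'   `viral_hit`, `bacterial_hit`) and `n_bacterial_only` (count of reads
#'   with bacterial homology only).
#' @export
assign_all <- function(viral_hits, bacterial_hits, tree,
                       thresholds = filter_thresholds(), tie_margin = 0,
                       sample_id = NA_character_) {
  fv <- filter_hits(viral_hits, thresholds)
  fb <- filter_hits(bacterial_hits, thresholds)
  bact_queries <- unique(fb$query_id)

  if (!nrow(fv)) {
    empty <- data.frame(sample_id = character(0), query_id = character(0),
                        taxon_id = character(0),
                        resolution_rank = character(0),
                        co_optimal_count = integer(0),
                        viral_class = character(0), viral_hit = logical(0),
                        bacterial_hit = logical(0), stringsAsFactors = FALSE)
    return(list(assignments = empty,
                n_bacterial_only = length(bact_queries)))
  }

  counts <- table(fv$query_id)
  multi <- names(counts)[counts > 1L]

  # fast path: queries with a single retained viral hit
  single_rows <- fv[!(fv$query_id %in% multi), , drop = FALSE]
  if (nrow(single_rows)) {
    taxa <- .subject_taxon(tree, single_rows$subject_id)
    singles <- data.frame(
      query_id = single_rows$query_id,
      taxon_id = taxa,
      resolution_rank = tree$nodes$rank[match(taxa, tree$nodes$taxon_id)],
      co_optimal_count = 1L,
      viral_class = .subject_class(tree, single_rows$subject_id),
      stringsAsFactors = FALSE)
  } else {
    singles <- NULL
  }
  if (length(multi)) {
    parts <- split(fv[fv$query_id %in% multi, , drop = FALSE],
                   fv$query_id[fv$query_id %in% multi])
    multis <- do.call(rbind, lapply(parts, assign_read, tree = tree,
                                    tie_margin = tie_margin))
  } else {
    multis <- NULL
  }
  asg <- rbind(singles, multis)
  rownames(asg) <- NULL
  asg$viral_hit <- TRUE
  asg$bacterial_hit <- asg$query_id %in% bact_queries
  asg <- cbind(sample_id = sample_id, asg, stringsAsFactors = FALSE)
  n_bact_only <- length(setdiff(bact_queries, asg$query_id))
  list(assignments = asg, n_bacterial_only = n_bact_only)
}
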