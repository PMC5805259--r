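# Taxon-by-sample count tables (OTU tables), relative abundances,
# presence/absence, and rarefaction subsampling.

#' Construct a taxon-by-sample count table
#'
#' @param counts non-negative integer matrix, taxa (rows, lineage labels)
#'   by samples (columns).
#' @param rank the taxonomic rank of the rows, `"family"` or `"species"`.
#' @param metadata optional data.frame with `sample_id` and `sex` covering
#'   the columns.
#' @return an object of class `taxon_table`.
#' @export
taxon_table <- function(counts, rank = c("species", "family"),
                        metadata = NULL) {
  rank <- match.arg(rank)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts in taxon table")
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon labels")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample labels")
  storage.mode(counts) <- "integer"
  if (!is.null(metadata)) {
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                         drop = FALSE]
    if (anyNA(metadata$sample_id)) {
      stop("metadata does not cover every sample column")
    }
  }
  structure(list(counts = counts, rank = rank, metadata = metadata),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("taxon_table [", x$rank, "]: ", nrow(x$counts), " taxa x ",
      ncol(x$counts), " samples, ", sum(x$counts), " reads\n", sep = "")
  invisible(x)
}

#' Build a taxon-by-sample table from read assignments
#'
#' Each assignment contributes one count to its ancestor at the target
#' rank; assignments resolved shallower than the target rank, or
#' `UNDETERMINED`, accrue to the `UNDETERMINED` row, so column sums always
#' equal the number of assigned reads per sample in the selected pool.
#'
#' @param assignments assignment data.frame from [assign_all()] (may pool
#'   several samples; needs `sample_id`).
#' @param tree a [virome_taxonomy()].
#' @param rank target rank, `"family"` or `"species"`.
#' @param pool homology pool to tabulate: `"all"`, `"virus_only"` or
#'   `"virus_and_bacteria"`.
#' @param metadata optional sample metadata; also fixes the column set and
#'   order (samples with no reads get zero columns).
#' @return a [taxon_table()] whose rows are lineage strings at `rank` plus
#'   an `UNDETERMINED` row.
#' @export
build_taxon_table <- function(assignments, tree,
                              rank = c("species", "family"),
                              pool = c("all", "virus_only",
                                       "virus_and_bacteria"),
                              metadata = NULL) {
  rank <- match.arg(rank)
  pool <- match.arg(pool)
  asg <- switch(pool,
    all = assignments,
    virus_only = assignments[!assignments$bacterial_hit, , drop = FALSE],
    virus_and_bacteria = assignments[assignments$bacterial_hit, ,
                                     drop = FALSE])

  # roll each assignment up (or down to UNDETERMINED) at the target rank
  roll <- rep(UNDETERMINED, nrow(asg))
  det <- asg$taxon_id != UNDETERMINED
  if (any(det)) {
    uniq <- unique(asg$taxon_id[det])
    anc <- vapply(uniq, function(id) tax_ancestor_at_rank(tree, id, rank),
                  character(1))
    lab <- ifelse(is.na(anc), UNDETERMINED,
                  vapply(anc, function(id) {
                    if (is.na(id)) UNDETERMINED else
                      tax_lineage(tree, id, to_rank = rank)
                  }, character(1)))
    roll[det] <- lab[match(asg$taxon_id[det], uniq)]
  }
  samples <- if (!is.null(metadata)) metadata$sample_id else
    sort(unique(asg$sample_id))
  taxa <- sort(setdiff(unique(roll), UNDETERMINED))
  taxa <- c(taxa, UNDETERMINED)
  counts <- table(factor(roll, levels = taxa),
                  factor(asg$sample_id, levels = samples))
  m <- matrix(as.integer(counts), nrow = length(taxa),
              dimnames = list(taxa, samples))
  taxon_table(m, rank = rank, metadata = metadata)
}

#' Per-sample relative abundances
#'
#' @param table a [taxon_table()].
#' @return numeric matrix of proportions; each nonzero column sums to 1;
#'   all-zero columns are left at zero and listed in the
#'   `"zero_samples"` attribute.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  counts <- table$counts
  tot <- colSums(counts)
  if (all(tot == 0)) stop("relative_abundance: table has no reads")
  props <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/")
  attr(props, "zero_samples") <- colnames(counts)[tot == 0]
  props
}

#' Presence/absence matrix
#'
#' @param table a [taxon_table()].
#' @param min_count minimum count (inclusive) for presence; default 1.
#' @return binary integer matrix of the same shape.
#' @export
presence_absence <- function(table, min_count = 1L) {
  stopifnot(inherits(table, "taxon_table"), min_count >= 1)
  (table$counts >= min_count) * 1L
}

#' Rarefy a taxon table to a fixed depth
#'
#' Samples with fewer reads than `depth` are dropped (and listed in the
#' `dropped_samples` attribute); every retained sample is subsampled
#' without replacement to exactly `depth` reads (multivariate
#' hypergeometric, via `vegan::rrarefy`). Reproducible under a fixed seed.
#'
#' @param table a [taxon_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed for the subsampling.
#' @return a [taxon_table()] with attribute `dropped_samples`; when no
#'   sample reaches `depth` the table has zero columns and a warning is
#'   raised.
#' @export
subsample_table <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "taxon_table"), depth >= 1)
  counts <- table$counts
  tot <- colSums(counts)
  keep <- tot >= depth
  dropped <- colnames(counts)[!keep]
  kept <- counts[, keep, drop = FALSE]
  if (!ncol(kept)) {
    warning("subsample_table: no sample reaches depth ", depth)
    out <- taxon_table(kept, rank = table$rank,
                       metadata = if (is.null(table$metadata)) NULL else
                         table$metadata[keep, , drop = FALSE])
    attr(out, "dropped_samples") <- dropped
    return(out)
  }
  set.seed(seed)
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic
  # against non-count data); our inputs are genuine counts
  rar <- withCallingHandlers(
    t(vegan::rrarefy(t(kept), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(rar) <- "integer"
  md <- if (is.null(table$metadata)) NULL else
    table$metadata[keep, , drop = FALSE]
  out <- taxon_table(rar, rank = table$rank, metadata = md)
  attr(out, "dropped_samples") <- dropped
  out
}
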