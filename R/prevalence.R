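# Core-virome prevalence analysis: per-taxon occurrence counts across
# samples, four-tier prevalence categories, singleton detection, and
# category-distribution summaries.
#
# Category boundaries (fraction of samples where the taxon is present):
#   high        : fraction > 0.75           ("core" taxa)
#   medium_high : 0.50 <= fraction <= 0.75
#   medium_low  : 0.25 <= fraction < 0.50
#   low         : fraction < 0.25
# The stated 50-75% and 25-50% ranges overlap at their shared endpoints;
# we resolve each boundary to the upper tier (>= 0.50 is medium_high,
# >= 0.25 is medium_low) while "core" stays strictly above 75%.

PREVALENCE_CATEGORIES <- c("high", "medium_high", "medium_low", "low")

#' Prevalence category of an occurrence count
#'
#' @param occurrences number of samples where the taxon is present
#'   (vectorised).
#' @param n_samples total number of samples.
#' @return character vector of categories; `NA` for zero occurrences
#'   (absent taxa carry no category).
#' @export
categorize_prevalence <- function(occurrences, n_samples) {
  stopifnot(n_samples >= 1, all(occurrences >= 0),
            all(occurrences <= n_samples))
  f <- occurrences / n_samples
  out <- rep(NA_character_, length(f))
  out[f > 0 & f < 0.25] <- "low"
  out[f >= 0.25 & f < 0.50] <- "medium_low"
  out[f >= 0.50 & f <= 0.75] <- "medium_high"
  out[f > 0.75] <- "high"
  out
}

#' Per-taxon occurrence counts and prevalence records
#'
#' Row-sums a presence/absence matrix into per-taxon occurrence counts and
#' attaches the prevalence category and singleton flag. The
#' `UNDETERMINED` row, if present, is excluded: only named taxa take part
#' in core-virome categorisation.
#'
#' @param presence binary taxa-by-samples matrix from
#'   [presence_absence()].
#' @return data.frame with columns `taxon`, `occurrences`, `n_samples`,
#'   `fraction`, `category`, `singleton`.
#' @export
occurrence_counts <- function(presence) {
  stopifnot(is.matrix(presence), ncol(presence) >= 1)
  presence <- presence[setdiff(rownames(presence), UNDETERMINED), ,
                       drop = FALSE]
  n <- ncol(presence)
  occ <- as.integer(rowSums(presence))
  data.frame(taxon = rownames(presence),
             occurrences = occ,
             n_samples = n,
             fraction = occ / n,
             category = categorize_prevalence(occ, n),
             singleton = occ == 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Distribution of taxa over prevalence categories
#'
#' Fractions are taken over taxa with at least one occurrence; the
#' singleton fraction (taxa seen in exactly one sample) is reported
#' separately and overlaps the low category.
#'
#' @param records data.frame from [occurrence_counts()].
#' @return list with `n_taxa` (categorised taxa), `fractions` (named over
#'   the four categories, summing to 1), `counts`, and
#'   `singleton_fraction`.
#' @export
category_distribution <- function(records) {
  rec <- records[records$occurrences >= 1L, , drop = FALSE]
  if (!nrow(rec)) stop("category_distribution: no taxon with occurrences")
  tab <- table(factor(rec$category, levels = PREVALENCE_CATEGORIES))
  list(n_taxa = nrow(rec),
       counts = stats::setNames(as.integer(tab), names(tab)),
       fractions = stats::setNames(as.numeric(tab) / nrow(rec), names(tab)),
       singleton_fraction = mean(rec$singleton))
}

#' Occupancy histogram (taxa per occurrence count)
#'
#' How many taxa occur in exactly 1, 2, ..., n samples — the basis of
#' occupancy histograms over prevalence categories.
#'
#' @param records data.frame from [occurrence_counts()].
#' @return data.frame with `occurrences`, `n_taxa`, `category`.
#' @export
occupancy_histogram <- function(records) {
  rec <- records[records$occurrences >= 1L, , drop = FALSE]
  n <- rec$n_samples[1]
  occ <- seq_len(n)
  data.frame(occurrences = occ,
             n_taxa = vapply(occ, function(k) sum(rec$occurrences == k), 1L),
             category = categorize_prevalence(occ, n),
             stringsAsFactors = FALSE)
}

#' Write prevalence records to TSV
#' @param records data.frame from [occurrence_counts()].
#' @param path output path.
#' @export
write_prevalence <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
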