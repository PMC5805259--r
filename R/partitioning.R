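# Partition viral read assignments by reference class (prophage /
# bacteriophage / eukaryotic virus) and by dual-database homology
# (virus-only vs virus-and-bacteria), and summarise the proportions.

HOMOLOGY_CLASSES <- c("virus_only", "virus_and_bacteria", "all")

#' Viral class of a read assignment
#'
#' The class recorded during assignment: the subject-map annotation of the
#' winning hit, or, for LCA-level assignments, the majority class over the
#' co-optimal hit set with ties resolved by the top-ranked hit.
#'
#' @param assignment a one-row assignment data.frame from [assign_read()]
#'   or a row of [assign_all()]'s `assignments`.
#' @return one of `"prophage"`, `"bacteriophage"`, `"eukaryotic_virus"`.
#' @export
viral_class_of <- function(assignment) {
  cls <- assignment$viral_class
  if (is.null(cls) || anyNA(cls)) {
    stop("annotation error: assignment carries no viral_class")
  }
  cls
}

#' Summarise viral read counts by homology pool and viral class
#'
#' Builds the 3 x 3 count table (homology pool: virus_only,
#' virus_and_bacteria, all) x (viral class: prophage, bacteriophage,
#' eukaryotic_virus) and the within-pool percentages. The `all` pool is
#' the cell-wise sum of the other two.
#'
#' @param assignments assignment data.frame from [assign_all()] (needs
#'   `viral_class` and `bacterial_hit` columns).
#' @return an object of class `partition_summary` with elements `counts`
#'   (integer matrix, pools x classes), `proportions` (percent within each
#'   pool; all-`NA` row for an empty pool), and `pool_totals`.
#' @export
partition_summary <- function(assignments) {
  counts <- matrix(0L, nrow = 3, ncol = length(VIRAL_CLASSES),
                   dimnames = list(HOMOLOGY_CLASSES, VIRAL_CLASSES))
  if (nrow(assignments)) {
    cls <- factor(viral_class_of(assignments), levels = VIRAL_CLASSES)
    pool <- factor(ifelse(assignments$bacterial_hit, "virus_and_bacteria",
                          "virus_only"),
                   levels = HOMOLOGY_CLASSES[1:2])
    tab <- table(pool, cls)
    counts["virus_only", ] <- as.integer(tab["virus_only", ])
    counts["virus_and_bacteria", ] <- as.integer(tab["virus_and_bacteria", ])
  }
  counts["all", ] <- counts["virus_only", ] + counts["virus_and_bacteria", ]
  totals <- rowSums(counts)
  props <- counts / ifelse(totals > 0, totals, NA_real_) * 100
  structure(list(counts = counts, proportions = props,
                 pool_totals = totals),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("Viral read partition (counts):\n")
  print(x$counts)
  cat("\nWithin-pool percentages:\n")
  print(round(x$proportions, 1))
  invisible(x)
}

#' Read-accounting totals across homology pools
#'
#' The viral-read total is the sum of the virus-only and
#' virus-and-bacteria pools; every assigned read is in exactly one pool.
#'
#' @param ps a [partition_summary()].
#' @return named numeric: `virus_only`, `virus_and_bacteria`, `viral_total`.
#' @export
read_accounting <- function(ps) {
  stopifnot(inherits(ps, "partition_summary"))
  c(virus_only = unname(ps$pool_totals["virus_only"]),
    virus_and_bacteria = unname(ps$pool_totals["virus_and_bacteria"]),
    viral_total = unname(ps$pool_totals["virus_only"] +
                           ps$pool_totals["virus_and_bacteria"]))
}

#' Write a partition summary as TSV and JSON
#' @param ps a [partition_summary()].
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_partition_summary <- function(ps, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(ps, "partition_summary"))
  if (!is.null(tsv_path)) {
    df <- data.frame(homology_class = rep(rownames(ps$counts),
                                          each = ncol(ps$counts)),
                     viral_class = rep(colnames(ps$counts),
                                       times = nrow(ps$counts)),
                     reads = as.vector(t(ps$counts)),
                     percent = round(as.vector(t(ps$proportions)), 1))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    obj <- list(counts = apply(ps$counts, 1, as.list, simplify = FALSE),
                proportions = apply(ps$proportions, 1, as.list,
                                    simplify = FALSE),
                pool_totals = as.list(ps$pool_totals))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(ps)
}
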