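# Readers/writers for the tabular formats the pipeline touches:
# 12/13-column BLAST tabular hit files, taxonomy TSVs, sample metadata, and
# taxon-by-sample tables (TSV and sparse BIOM 1.0 JSON).

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_openings",
                 "q_start", "q_end", "s_start", "s_end",
                 "e_value", "bit_score")

#' Read a tabular alignment-hit file (BLAST outfmt 6 dialect)
#'
#' Parses a 12-column tab-separated BLAST hit table, optionally extended
#' with a 13th `qlen` column. Every hit must end up with a read length
#' (`query_length`): either from the 13th column or from a separate
#' two-column read-length table (`query_id`, `query_length`), because the
#' downstream filter uses `alignment_length / query_length` as the read
#' coverage fraction. Lines starting with `#` are ignored.
#'
#' @param path file path to the hit table.
#' @param db_label which database the hits are against; `"viral"` or
#'   `"bacterial"`; attached to every row.
#' @param query_lengths optional read-length source: a data.frame with
#'   columns `query_id` and `query_length`, a named numeric vector, or a
#'   path to a two-column TSV. Required when the table has only 12 columns.
#' @return data.frame of hits, one per input row in input order, with the
#'   standard columns plus `query_length` and `db_label`.
#' @export
read_hit_table <- function(path, db_label = c("viral", "bacterial"),
                           query_lengths = NULL) {
  db_label <- match.arg(db_label)
  if (!file.exists(path)) stop("hit table not found: ", path)

  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(BLAST6_COLS)))
    names(out) <- BLAST6_COLS
    out$query_length <- integer(0)
    out$db_label <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(12L, 13L)))
  if (length(bad)) {
    stop("malformed hit row at line ", line_no[bad[1]], ": expected 12 or 13 ",
         "tab-separated fields, found ", nf[bad[1]])
  }
  if (length(unique(nf)) > 1L) {
    stop("malformed hit table: mixed 12- and 13-column rows (first ",
         "divergence at line ", line_no[which(nf != nf[1])[1]], ")")
  }
  ncol_in <- nf[1]
  m <- matrix(unlist(fields), ncol = ncol_in, byrow = TRUE)
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     stringsAsFactors = FALSE)
  num_cols <- c(percent_identity = 3, alignment_length = 4, mismatches = 5,
                gap_openings = 6, q_start = 7, q_end = 8, s_start = 9,
                s_end = 10, e_value = 11, bit_score = 12)
  for (nm in names(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, num_cols[[nm]]]))
    if (anyNA(v)) {
      stop("malformed hit row at line ", line_no[which(is.na(v))[1]],
           ": non-numeric ", nm)
    }
    hits[[nm]] <- v
  }
  hits$alignment_length <- as.integer(hits$alignment_length)

  if (ncol_in == 13L) {
    qlen <- suppressWarnings(as.numeric(m[, 13]))
    if (anyNA(qlen)) {
      stop("malformed hit row at line ", line_no[which(is.na(qlen))[1]],
           ": non-numeric qlen")
    }
    hits$query_length <- as.integer(qlen)
  } else {
    if (is.null(query_lengths)) {
      stop("configuration error: 12-column hit table requires a ",
           "query_lengths source (13th qlen column or read-length table)")
    }
    ql <- .as_query_length_map(query_lengths)
    idx <- match(hits$query_id, names(ql))
    if (anyNA(idx)) {
      stop("configuration error: missing query_length for ",
           sum(is.na(idx)), " quer", if (sum(is.na(idx)) == 1) "y" else "ies",
           " (first: ", hits$query_id[which(is.na(idx))[1]], ")")
    }
    hits$query_length <- as.integer(ql[idx])
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop("percent_identity outside [0, 100]")
  }
  if (any(hits$e_value < 0)) stop("negative e_value")
  if (any(hits$alignment_length < 1)) stop("alignment_length < 1")
  hits$db_label <- db_label
  hits
}

.as_query_length_map <- function(query_lengths) {
  if (is.character(query_lengths) && length(query_lengths) == 1L &&
      file.exists(query_lengths)) {
    tab <- utils::read.delim(query_lengths, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    names(tab)[1:2] <- c("query_id", "query_length")
    query_lengths <- tab
  }
  if (is.data.frame(query_lengths)) {
    out <- stats::setNames(as.numeric(query_lengths$query_length),
                           as.character(query_lengths$query_id))
  } else if (is.numeric(query_lengths) && !is.null(names(query_lengths))) {
    out <- query_lengths
  } else {
    stop("query_lengths must be a data.frame, named vector, or TSV path")
  }
  if (any(out < 1)) stop("query_length must be >= 1")
  out
}

#' Read a taxonomy from node and subject-map TSV files
#'
#' @param nodes_path TSV with header columns `taxon_id`, `name`, `rank`,
#'   `parent_id` (empty/NA parent marks a root).
#' @param subjects_path TSV with header columns `subject_id`, `taxon_id`,
#'   `viral_class`.
#' @return a validated [virome_taxonomy()].
#' @export
read_taxonomy <- function(nodes_path, subjects_path) {
  nodes <- utils::read.delim(nodes_path, sep = "\t", stringsAsFactors = FALSE,
                             na.strings = c("NA", ""), quote = "")
  subjects <- utils::read.delim(subjects_path, sep = "\t",
                                stringsAsFactors = FALSE, quote = "")
  virome_taxonomy(nodes, subjects)
}

#' Write a taxonomy to node and subject-map TSV files
#' @param tree a `virome_taxonomy`
#' @param nodes_path,subjects_path output file paths
#' @export
write_taxonomy <- function(tree, nodes_path, subjects_path) {
  utils::write.table(tree$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(tree$subjects, subjects_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(nodes_path, subjects_path))
}

#' Read sample metadata (sample ID and sex)
#'
#' QIIME-mapping-like TSV: first column is the sample ID (a leading `#` on
#' the header is tolerated), and a `sex` column restricted to `F`/`M`.
#'
#' @param path metadata TSV path.
#' @return data.frame with columns `sample_id`, `sex`.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           quote = "", check.names = FALSE)
  names(tab)[1] <- sub("^#", "", names(tab)[1])
  names(tab)[1] <- "sample_id"
  if (!"sex" %in% names(tab)) stop("metadata needs a 'sex' column")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         tab$sample_id[duplicated(tab$sample_id)][1])
  }
  bad <- setdiff(unique(tab$sex), c("F", "M"))
  if (length(bad)) {
    stop("sex must be 'F' or 'M'; found: ", paste(bad, collapse = ", "))
  }
  tab[, c("sample_id", "sex")]
}

#' Write a taxon-by-sample table to TSV or BIOM 1.0 JSON
#'
#' The TSV layout is taxa-by-samples with the full lineage string as the
#' first (`taxon`) column. The BIOM output follows the Biological
#' Observation Matrix 1.0 JSON schema with `matrix_type` "sparse"
#' (row, column, value triplets; zero rows keep their row index entry but
#' contribute no triplets).
#'
#' @param table a [taxon_table()].
#' @param path output file path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(table, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "taxon_table"))
  counts <- table$counts
  if (!length(counts)) stop("cannot write an empty taxon table")
  if (format == "tsv") {
    df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nz <- which(counts != 0, arr.ind = TRUE)
    ord <- order(nz[, 1], nz[, 2])
    nz <- nz[ord, , drop = FALSE]
    data_triplets <- lapply(seq_len(nrow(nz)), function(i) {
      c(nz[i, 1] - 1L, nz[i, 2] - 1L, counts[nz[i, 1], nz[i, 2]])
    })
    obj <- list(
      id = NULL,
      format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table",
      generated_by = paste0("oralvirome ",
                            as.character(utils::packageVersion("oralvirome"))),
      date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      rows = lapply(rownames(counts),
                    function(id) list(id = id, metadata = NULL)),
      columns = lapply(colnames(counts),
                       function(id) list(id = id, metadata = NULL)),
      matrix_type = "sparse",
      matrix_element_type = "int",
      shape = dim(counts),
      data = data_triplets
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  }
  invisible(path)
}

#' Read a taxon-by-sample table written by [write_taxon_table()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"biom_json"`; BIOM files are parsed with the
#'   biomformat package.
#' @param rank rank label to attach to the returned table.
#' @param metadata optional sample metadata data.frame.
#' @return a [taxon_table()].
#' @export
read_taxon_table <- function(path, format = c("tsv", "biom_json"),
                             rank = "species", metadata = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE, quote = "")
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  } else {
    b <- biomformat::read_biom(path)
    counts <- as(biomformat::biom_data(b), "matrix")
  }
  storage.mode(counts) <- "integer"
  taxon_table(counts, rank = rank, metadata = metadata)
}
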