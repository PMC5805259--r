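# End-to-end orchestration: assign -> partition -> tables -> prevalence
# -> diversity for each (pool, rank, depth) combination, from a fixture
# directory laid out as written by write_fixture().

#' Pipeline configuration
#'
#' @param input_dir fixture directory (per-sample hit tables, taxonomy,
#'   metadata; the layout of [write_fixture()]).
#' @param output_dir directory for result files; created if needed.
#' @param thresholds a [filter_thresholds()].
#' @param tie_margin co-optimality margin for [assign_read()].
#' @param ranks ranks to tabulate (subset of `"family"`, `"species"`).
#' @param pools homology pools to analyse (subset of `"all"`,
#'   `"virus_only"`).
#' @param depths increasing rarefaction depths; the default pair mirrors
#'   a lenient and a strict subsampling regime.
#' @param n_permutations Monte Carlo permutations for group tests.
#' @param seed master integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir = file.path(input_dir,
                                                              "results"),
                            thresholds = filter_thresholds(),
                            tie_margin = 0,
                            ranks = c("family", "species"),
                            pools = c("all", "virus_only"),
                            depths = c(157, 700),
                            n_permutations = 999,
                            seed = 1L) {
  stopifnot(all(ranks %in% c("family", "species")),
            all(pools %in% c("all", "virus_only", "virus_and_bacteria")),
            all(depths >= 1), !is.unsorted(depths),
            n_permutations >= 99)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 thresholds = thresholds, tie_margin = tie_margin,
                 ranks = ranks, pools = pools, depths = depths,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; threshold
#' fields may be given under `thresholds:` as `max_evalue`,
#' `min_identity`, `min_coverage`.
#'
#' @param path YAML file path.
#' @param input_dir overrides the `input_dir` key when non-NULL.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, input_dir = NULL) {
  y <- yaml::read_yaml(path)
  thr <- do.call(filter_thresholds, as.list(y$thresholds))
  args <- y[setdiff(names(y), "thresholds")]
  if (!is.null(input_dir)) args$input_dir <- input_dir
  args$thresholds <- thr
  do.call(pipeline_config, args)
}

#' Run the virome profiling pipeline end to end
#'
#' Reads the fixture directory, assigns every read, partitions the viral
#' pool, builds family/species taxon tables for each homology pool,
#' categorises prevalence, rarefies at each configured depth, and
#' compares Shannon alpha and Bray-Curtis beta diversity between the sex
#' groups. Writes per-stage TSVs and a machine-readable `summary.json`
#' under the output directory and returns the summary invisibly.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  inputs <- stage("load", {
    md <- read_sample_metadata(file.path(config$input_dir, "metadata.tsv"))
    tree <- read_taxonomy(
      file.path(config$input_dir, "taxonomy_nodes.tsv"),
      file.path(config$input_dir, "taxonomy_subjects.tsv"))
    list(md = md, tree = tree)
  })
  md <- inputs$md; tree <- inputs$tree

  asg <- stage("assign", {
    per_sample <- lapply(md$sample_id, function(s) {
      vh <- read_hit_table(
        file.path(config$input_dir, paste0("viral_hits_", s, ".tsv")),
        db_label = "viral")
      bh <- read_hit_table(
        file.path(config$input_dir, paste0("bacterial_hits_", s, ".tsv")),
        db_label = "bacterial")
      assign_all(vh, bh, tree, thresholds = config$thresholds,
                 tie_margin = config$tie_margin, sample_id = s)
    })
    list(assignments = do.call(rbind,
                               lapply(per_sample, `[[`, "assignments")),
         n_bacterial_only = sum(vapply(per_sample, `[[`, 0,
                                       "n_bacterial_only")))
  })

  part <- stage("partition", {
    ps <- partition_summary(asg$assignments)
    write_partition_summary(
      ps, tsv_path = file.path(config$output_dir, "partition_summary.tsv"),
      json_path = file.path(config$output_dir, "partition_summary.json"))
    ps
  })

  prevalence_out <- list()
  diversity_out <- list()
  for (pool in config$pools) {
    for (rank in config$ranks) {
      key <- paste(pool, rank, sep = ".")
      tt <- stage(paste0("tabulate:", key), {
        tt <- build_taxon_table(asg$assignments, tree, rank = rank,
                                pool = pool, metadata = md)
        write_taxon_table(tt, file.path(config$output_dir,
                                        paste0("table_", key, ".tsv")),
                          format = "tsv")
        write_taxon_table(tt, file.path(config$output_dir,
                                        paste0("table_", key, ".biom")),
                          format = "biom_json")
        tt
      })
      prevalence_out[[key]] <- stage(paste0("prevalence:", key), {
        rec <- occurrence_counts(presence_absence(tt))
        write_prevalence(rec, file.path(config$output_dir,
                                        paste0("prevalence_", key, ".tsv")))
        category_distribution(rec)
      })
      for (depth in config$depths) {
        dkey <- paste(key, depth, sep = ".")
        diversity_out[[dkey]] <- stage(paste0("diversity:", dkey), {
          rt <- subsample_table(tt, depth, seed = config$seed)
          dropped <- attr(rt, "dropped_samples")
          utils::write.table(
            data.frame(sample_id = dropped),
            file.path(config$output_dir, paste0("dropped_", dkey, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
          if (ncol(rt$counts) < 4 ||
              length(unique(rt$metadata$sex)) < 2 ||
              any(table(rt$metadata$sex) < 2)) {
            list(retained = colnames(rt$counts), alpha = NULL, beta = NULL,
                 note = "too few samples per group after rarefaction")
          } else {
            alpha <- alpha_diversity(rt)
            ac <- compare_alpha(alpha,
                                stats::setNames(rt$metadata$sex,
                                                rt$metadata$sample_id),
                                n_permutations = config$n_permutations,
                                seed = config$seed)
            utils::write.table(
              ac, file.path(config$output_dir,
                            paste0("alpha_compare_", dkey, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
            dm <- bray_curtis_matrix(rt)
            bc <- compare_beta(dm,
                               stats::setNames(rt$metadata$sex,
                                               rt$metadata$sample_id),
                               n_permutations = config$n_permutations,
                               seed = config$seed)
            utils::write.table(
              bc$comparisons,
              file.path(config$output_dir,
                        paste0("beta_compare_", dkey, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
            list(retained = colnames(rt$counts),
                 n_retained = ncol(rt$counts),
                 alpha = ac, beta = bc$comparisons)
          }
        })
      }
    }
  }

  acc <- read_accounting(part)
  summary <- list(
    seed = config$seed,
    read_accounting = c(as.list(acc),
                        list(bacterial_reads = asg$n_bacterial_only)),
    partition = list(counts = apply(part$counts, 1, as.list,
                                    simplify = FALSE),
                     proportions = apply(part$proportions, 1, as.list,
                                         simplify = FALSE)),
    prevalence = prevalence_out,
    diversity = lapply(diversity_out, function(d) {
      list(n_retained = if (is.null(d$n_retained)) length(d$retained) else
        d$n_retained,
        alpha_p_raw = if (is.null(d$alpha)) NULL else d$alpha$p_raw,
        alpha_p_adjusted = if (is.null(d$alpha)) NULL else
          d$alpha$p_adjusted,
        beta_p_bonferroni = if (is.null(d$beta)) NULL else
          d$beta$p_bonferroni)
    }))
  jsonlite::write_json(summary, file.path(config$output_dir,
                                          "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(summary)
}
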