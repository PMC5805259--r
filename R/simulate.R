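# Synthetic virome fixtures with ground truth: a rank-labelled taxonomy
# with classed reference subjects, a multi-sample community (core taxa
# plus a singleton-dominated tail), and noisy dual-database alignment-hit
# tables. Every stage of the pipeline can be exercised against the
# generating parameters.

#' Simulate a viral taxonomy with classed reference subjects
#'
#' Families are distributed round-robin over orders; species hang directly
#' off their family (the genus rank is left undetermined, as is common in
#' viral reference taxonomies). Each family is assigned one viral class
#' (prophage / bacteriophage / eukaryotic virus) drawn from `class_mix`,
#' and each species gets exactly one reference subject carrying that
#' class.
#'
#' @param n_families number of families (>= 1).
#' @param species_per_family species per family (>= 1).
#' @param class_mix named proportions over the viral classes; must be
#'   non-negative and sum to 1.
#' @param n_orders number of order-level roots.
#' @param seed integer seed.
#' @return a [virome_taxonomy()].
#' @export
simulate_taxonomy <- function(n_families = 12, species_per_family = 5,
                              class_mix = c(prophage = 0.5,
                                            bacteriophage = 0.3,
                                            eukaryotic_virus = 0.2),
                              n_orders = 3, seed = 1L) {
  stopifnot(n_families >= 1, species_per_family >= 1, n_orders >= 1)
  if (is.null(names(class_mix)) ||
      !setequal(names(class_mix), VIRAL_CLASSES) ||
      any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix must be named over ",
         paste(VIRAL_CLASSES, collapse = ", "), " and sum to 1")
  }
  set.seed(seed)
  orders <- data.frame(
    taxon_id = sprintf("o%02d", seq_len(n_orders)),
    name = sprintf("Order%02d", seq_len(n_orders)),
    rank = "order", parent_id = NA_character_,
    stringsAsFactors = FALSE)
  fam_order <- rep(orders$taxon_id, length.out = n_families)
  families <- data.frame(
    taxon_id = sprintf("f%02d", seq_len(n_families)),
    name = sprintf("Family%02d", seq_len(n_families)),
    rank = "family", parent_id = fam_order,
    stringsAsFactors = FALSE)
  # one class per family: deterministic counts from the mix, shuffled
  n_per_class <- diff(c(0, round(cumsum(class_mix) * n_families)))
  fam_class <- sample(rep(names(class_mix), times = n_per_class))
  k <- 0L
  sp_list <- lapply(seq_len(n_families), function(i) {
    ids <- sprintf("s%03d", (i - 1L) * species_per_family +
                     seq_len(species_per_family))
    data.frame(taxon_id = ids,
               name = sprintf("Virus_%s_%02d", families$name[i],
                              seq_len(species_per_family)),
               rank = "species", parent_id = families$taxon_id[i],
               stringsAsFactors = FALSE)
  })
  species <- do.call(rbind, sp_list)
  nodes <- rbind(orders, families, species)
  subjects <- data.frame(
    subject_id = paste0("ref_", species$taxon_id),
    taxon_id = species$taxon_id,
    viral_class = rep(fam_class, each = species_per_family),
    stringsAsFactors = FALSE)
  virome_taxonomy(nodes, subjects)
}

#' Community model: per-taxon prevalence/abundance and noise parameters
#'
#' Encodes the study conditions the generator emulates: a 72-sample
#' cohort with a balanced sex split, a small core block of taxa present
#' in (almost) every sample plus a long singleton-dominated tail, a
#' lognormal abundance spectrum, a prophage-dominated read pool, and
#' class-dependent probabilities that a viral read also matches the
#' bacterial database.
#'
#' Default read-pool shares (prophage 92%, bacteriophage 5%, eukaryotic
#' virus 3%) and the bacterial-homology probabilities (0.945 / 0.642 /
#' 0.02) jointly place about 90% of viral reads in the virus-and-bacteria
#' pool, with that pool strongly prophage-skewed and the virus-only pool
#' roughly balanced between prophages and the rest — the regime typical
#' of oral viromes profiled against prophage-containing databases.
#'
#' @param tree a [virome_taxonomy()] (defines the taxa).
#' @param n_samples cohort size (default 72).
#' @param sex_split named proportions for F/M (default balanced).
#' @param core_fraction fraction of species in the core block.
#' @param core_prob_range prevalence probability range for core taxa.
#' @param tail_prob_range prevalence probability range for tail taxa
#'   (default lower bound `1/n_samples`).
#' @param abundance_meanlog,abundance_sdlog lognormal abundance-weight
#'   parameters.
#' @param reads_per_sample median viral reads per sample (default 2834).
#' @param depth_sdlog lognormal sd of the per-sample read depth around
#'   `reads_per_sample` (default 1.5, a wide spread under which a few
#'   samples fall below lenient rarefaction depths and more below strict
#'   ones); 0 gives every sample the same depth.
#' @param bacterial_only_per_sample reads per sample matching only the
#'   bacterial database (default 18608).
#' @param class_read_shares named expected read-pool shares per viral
#'   class; renormalised over the classes present in `tree`.
#' @param p_bacterial_homology named per-class probability that a viral
#'   read also retains a bacterial hit.
#' @param noise list of hit-noise parameters: `identity_mean`,
#'   `identity_sd` (truncated-normal percent identity), `coverage_shape1`,
#'   `coverage_shape2` (beta read-coverage), `fail_rate` (fraction of
#'   reads whose primary hit is forced below the identity threshold),
#'   `off_target_rate` (fraction of reads given a co-optimal hit to a
#'   sibling species, creating LCA cases).
#' @param seed integer seed for the per-taxon parameter draws.
#' @return an object of class `community_model`.
#' @export
community_model <- function(tree,
                            n_samples = 72,
                            sex_split = c(F = 0.5, M = 0.5),
                            core_fraction = 0.1,
                            core_prob_range = c(0.9, 1.0),
                            tail_prob_range = c(1 / n_samples, 0.2),
                            abundance_meanlog = 0,
                            abundance_sdlog = 1.5,
                            reads_per_sample = 2834,
                            depth_sdlog = 1.5,
                            bacterial_only_per_sample = 18608,
                            class_read_shares = c(prophage = 0.92,
                                                  bacteriophage = 0.05,
                                                  eukaryotic_virus = 0.03),
                            p_bacterial_homology = c(prophage = 0.945,
                                                     bacteriophage = 0.642,
                                                     eukaryotic_virus = 0.02),
                            noise = list(identity_mean = 95,
                                         identity_sd = 4,
                                         coverage_shape1 = 18,
                                         coverage_shape2 = 2,
                                         fail_rate = 0.02,
                                         off_target_rate = 0.02),
                            seed = 1L) {
  stopifnot(n_samples >= 2, reads_per_sample >= 1,
            bacterial_only_per_sample >= 0,
            core_fraction >= 0, core_fraction <= 1,
            all(p_bacterial_homology >= 0), all(p_bacterial_homology <= 1),
            abs(sum(sex_split) - 1) < 1e-9)
  if (any(class_read_shares < 0) ||
      abs(sum(class_read_shares) - 1) > 1e-9) {
    stop("class_read_shares must be non-negative and sum to 1")
  }
  core_prob_range <- sort(pmin(pmax(core_prob_range, 0), 1))
  tail_prob_range <- sort(pmin(pmax(tail_prob_range, 0), 1))
  sp <- tree$nodes[tree$nodes$rank == "species", , drop = FALSE]
  subj <- tree$subjects[match(sp$taxon_id, tree$subjects$taxon_id), ]
  n_taxa <- nrow(sp)
  set.seed(seed)
  # core block stratified by viral class: each class keeps at least one
  # core taxon (oral cohorts report core prophages, phages and
  # eukaryotic viruses alike), the rest proportional to class size
  is_core <- rep(FALSE, n_taxa)
  if (core_fraction > 0) {
    for (cl in unique(subj$viral_class)) {
      idx <- which(subj$viral_class == cl)
      k <- max(1L, round(core_fraction * length(idx)))
      is_core[sample(idx, min(k, length(idx)))] <- TRUE
    }
  }
  prev <- ifelse(is_core,
                 stats::runif(n_taxa, core_prob_range[1], core_prob_range[2]),
                 stats::runif(n_taxa, tail_prob_range[1], tail_prob_range[2]))
  taxa <- data.frame(taxon_id = sp$taxon_id,
                     subject_id = subj$subject_id,
                     viral_class = subj$viral_class,
                     core = is_core,
                     prevalence_prob = prev,
                     meanlog = abundance_meanlog,
                     sdlog = abundance_sdlog,
                     stringsAsFactors = FALSE)
  # sex labels: deterministic counts from the split, order shuffled
  n_f <- round(sex_split[["F"]] * n_samples)
  sex <- sample(c(rep("F", n_f), rep("M", n_samples - n_f)))
  metadata <- data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
                         sex = sex, stringsAsFactors = FALSE)
  structure(list(taxa = taxa, metadata = metadata, n_samples = n_samples,
                 reads_per_sample = reads_per_sample,
                 depth_sdlog = depth_sdlog,
                 bacterial_only_per_sample = bacterial_only_per_sample,
                 class_read_shares = class_read_shares,
                 p_bacterial_homology = p_bacterial_homology,
                 noise = noise, seed = seed),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("community_model:", nrow(x$taxa), "taxa,", x$n_samples, "samples,",
      x$reads_per_sample, "viral reads/sample\n")
  invisible(x)
}

#' Simulate the true taxon-by-sample community
#'
#' Presence is an independent Bernoulli draw per (taxon, sample) at the
#' taxon's prevalence probability. Present taxa receive lognormal
#' abundance weights; within each sample the weights are scaled so the
#' expected read share of each viral class matches
#' `model$class_read_shares` (renormalised over the classes present in
#' that sample), and reads are drawn by a multinomial at the sample's
#' depth (lognormal around `reads_per_sample` when `depth_sdlog > 0`).
#'
#' @param model a [community_model()].
#' @param seed integer seed.
#' @return list with `counts` (true species-by-sample read counts),
#'   `presence` (Bernoulli presence truth, which may include taxa that
#'   drew zero reads), and `metadata`.
#' @export
simulate_community <- function(model, seed = 1L) {
  stopifnot(inherits(model, "community_model"))
  set.seed(seed)
  taxa <- model$taxa
  n_t <- nrow(taxa)
  n_s <- model$n_samples
  presence <- matrix(stats::rbinom(n_t * n_s, 1L, taxa$prevalence_prob),
                     nrow = n_t,
                     dimnames = list(taxa$taxon_id,
                                     model$metadata$sample_id))
  counts <- matrix(0L, n_t, n_s,
                   dimnames = dimnames(presence))
  depths <- if (model$depth_sdlog > 0) {
    pmax(1L, as.integer(round(stats::rlnorm(n_s,
                                            log(model$reads_per_sample),
                                            model$depth_sdlog))))
  } else {
    rep(as.integer(model$reads_per_sample), n_s)
  }
  shares <- model$class_read_shares
  for (j in seq_len(n_s)) {
    pres <- which(presence[, j] == 1L)
    if (!length(pres)) next
    w <- stats::rlnorm(length(pres), taxa$meanlog[pres], taxa$sdlog[pres])
    cls <- taxa$viral_class[pres]
    cls_present <- intersect(names(shares), unique(cls))
    sh <- shares[cls_present] / sum(shares[cls_present])
    for (cl in cls_present) {
      sel <- cls == cl
      w[sel] <- w[sel] / sum(w[sel]) * sh[[cl]]
    }
    counts[pres, j] <- stats::rmultinom(1, depths[j], w / sum(w))[, 1]
  }
  list(counts = counts, presence = presence, metadata = model$metadata)
}

# truncated-normal identity draw on [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(mean, n))
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate dual-database alignment-hit tables from true counts
#'
#' Each true read receives one primary viral hit to its species' reference
#' subject, with percent identity, read coverage and e-value drawn from
#' the model's noise distributions; a `fail_rate` fraction is forced
#' below the identity threshold (emulating reads that drop out at
#' filtering). An `off_target_rate` fraction additionally receives a
#' co-optimal hit to a random sibling species (same identity and
#' alignment length), creating genuine LCA-to-family cases. Viral reads
#' also hit the bacterial database with the class-specific probability
#' `p_bacterial_homology`; `bacterial_only_per_sample` further reads per
#' sample hit only the bacterial database.
#'
#' @param community output of [simulate_community()].
#' @param model the [community_model()].
#' @param tree the [virome_taxonomy()] the model was built on.
#' @param seed integer seed.
#' @return list with `viral_hits`, `bacterial_hits` (hit data.frames in
#'   [read_hit_table()] layout), and `read_truth` (per-read truth:
#'   `query_id`, `sample_id`, `taxon_id`, `viral_class`, `passes_filter`,
#'   `has_bacterial`, `off_target`).
#' @export
simulate_hit_tables <- function(community, model, tree, seed = 1L) {
  stopifnot(inherits(model, "community_model"))
  set.seed(seed)
  counts <- community$counts
  taxa <- model$taxa
  noise <- model$noise

  # expand counts into one row per read
  nz <- which(counts > 0, arr.ind = TRUE)
  reps <- counts[nz]
  tax_idx <- rep(nz[, 1], reps)
  smp_idx <- rep(nz[, 2], reps)
  n_reads <- length(tax_idx)
  sample_id <- colnames(counts)[smp_idx]
  ord <- order(smp_idx)
  tax_idx <- tax_idx[ord]; sample_id <- sample_id[ord]
  read_no <- stats::ave(seq_len(n_reads), sample_id, FUN = seq_along)
  query_id <- sprintf("%s_r%06d", sample_id, read_no)

  qlen <- sample(150:400, n_reads, replace = TRUE)
  identity <- .rtruncnorm(n_reads, noise$identity_mean, noise$identity_sd)
  fails <- stats::runif(n_reads) < noise$fail_rate
  identity[fails] <- stats::runif(sum(fails), 50, 79.9)
  coverage <- stats::rbeta(n_reads, noise$coverage_shape1,
                           noise$coverage_shape2)
  aln_len <- pmax(1L, as.integer(round(coverage * qlen)))
  e_value <- 10^(-stats::runif(n_reads, 5, 40))
  bit_score <- round(1.8 * aln_len * identity / 100, 1)

  viral <- data.frame(
    query_id = query_id,
    subject_id = taxa$subject_id[tax_idx],
    percent_identity = round(identity, 2),
    alignment_length = aln_len,
    mismatches = as.integer(round((1 - identity / 100) * aln_len)),
    gap_openings = 0L,
    q_start = 1L, q_end = aln_len,
    s_start = 1L, s_end = aln_len,
    e_value = e_value, bit_score = bit_score,
    query_length = qlen,
    db_label = "viral", stringsAsFactors = FALSE)

  # off-target co-optimal hits to sibling species (same family)
  fam <- tree$nodes$parent_id[match(taxa$taxon_id, tree$nodes$taxon_id)]
  off <- which(stats::runif(n_reads) < noise$off_target_rate & !fails)
  got_sib <- rep(FALSE, n_reads)
  if (length(off)) {
    sib_rows <- list()
    for (i in off) {
      sibs <- which(fam == fam[tax_idx[i]] & seq_along(fam) != tax_idx[i])
      if (!length(sibs)) next
      row <- viral[i, ]
      row$subject_id <- taxa$subject_id[sibs[sample.int(length(sibs), 1)]]
      row$bit_score <- row$bit_score - 0.1
      sib_rows[[length(sib_rows) + 1L]] <- row
      got_sib[i] <- TRUE
    }
    if (length(sib_rows)) viral <- rbind(viral, do.call(rbind, sib_rows))
  }

  # bacterial homology for viral reads, by class
  p_bact <- model$p_bacterial_homology[taxa$viral_class[tax_idx]]
  has_bact <- stats::runif(n_reads) < p_bact
  n_b <- sum(has_bact)
  bact_from_viral <- if (n_b) data.frame(
    query_id = query_id[has_bact],
    subject_id = sprintf("bact_%03d", sample.int(200, n_b, replace = TRUE)),
    percent_identity = round(stats::runif(n_b, 82, 98), 2),
    alignment_length = as.integer(round(stats::runif(n_b, 0.78, 1) *
                                          qlen[has_bact])),
    mismatches = 0L, gap_openings = 0L,
    q_start = 1L, q_end = 1L, s_start = 1L, s_end = 1L,
    e_value = 10^(-stats::runif(n_b, 5, 40)),
    bit_score = round(stats::runif(n_b, 100, 500), 1),
    query_length = qlen[has_bact],
    db_label = "bacterial", stringsAsFactors = FALSE) else NULL

  # reads matching the bacterial database only
  n_bo_per <- model$bacterial_only_per_sample
  bact_only <- NULL
  if (n_bo_per > 0) {
    smp <- rep(colnames(counts), each = n_bo_per)
    n_bo <- length(smp)
    bqlen <- sample(150:400, n_bo, replace = TRUE)
    bact_only <- data.frame(
      query_id = sprintf("%s_b%06d", smp,
                         rep(seq_len(n_bo_per), times = ncol(counts))),
      subject_id = sprintf("bact_%03d", sample.int(200, n_bo,
                                                   replace = TRUE)),
      percent_identity = round(stats::runif(n_bo, 82, 98), 2),
      alignment_length = as.integer(round(stats::runif(n_bo, 0.78, 1) *
                                            bqlen)),
      mismatches = 0L, gap_openings = 0L,
      q_start = 1L, q_end = 1L, s_start = 1L, s_end = 1L,
      e_value = 10^(-stats::runif(n_bo, 5, 40)),
      bit_score = round(stats::runif(n_bo, 100, 500), 1),
      query_length = bqlen,
      db_label = "bacterial", stringsAsFactors = FALSE)
  }
  bacterial <- rbind(bact_from_viral, bact_only)
  if (is.null(bacterial)) {
    bacterial <- viral[0, ]
    bacterial$db_label <- character(0)
  }

  read_truth <- data.frame(
    query_id = query_id,
    sample_id = sample_id,
    taxon_id = taxa$taxon_id[tax_idx],
    viral_class = taxa$viral_class[tax_idx],
    passes_filter = round(identity, 2) >= 80 &
      aln_len / qlen >= 0.75 & e_value < 1e-3,
    has_bacterial = has_bact,
    off_target = got_sib,
    stringsAsFactors = FALSE)

  list(viral_hits = viral, bacterial_hits = bacterial,
       read_truth = read_truth)
}

#' Generate a complete fixture: taxonomy, community, and hit tables
#'
#' Convenience wrapper chaining [simulate_taxonomy()], [community_model()],
#' [simulate_community()] and [simulate_hit_tables()] under one seed.
#'
#' @param n_samples,reads_per_sample,bacterial_only_per_sample scale
#'   overrides passed to [community_model()].
#' @param n_families,species_per_family,class_mix taxonomy parameters.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param ... further arguments to [community_model()].
#' @return list with `tree`, `model`, `community`, `hits` (see
#'   [simulate_hit_tables()]).
#' @export
simulate_fixture <- function(n_samples = 72, reads_per_sample = 2834,
                             bacterial_only_per_sample = 18608,
                             n_families = 12, species_per_family = 5,
                             class_mix = c(prophage = 0.5,
                                           bacteriophage = 0.3,
                                           eukaryotic_virus = 0.2),
                             seed = 1L, ...) {
  tree <- simulate_taxonomy(n_families, species_per_family, class_mix,
                            seed = seed)
  model <- community_model(tree, n_samples = n_samples,
                           reads_per_sample = reads_per_sample,
                           bacterial_only_per_sample =
                             bacterial_only_per_sample,
                           seed = seed + 1L, ...)
  community <- simulate_community(model, seed = seed + 2L)
  hits <- simulate_hit_tables(community, model, tree, seed = seed + 3L)
  list(tree = tree, model = model, community = community, hits = hits)
}

#' Write a simulated fixture to a directory of plain-text files
#'
#' Produces per-sample 13-column hit tables (`viral_hits_<sample>.tsv`,
#' `bacterial_hits_<sample>.tsv`), the taxonomy (`taxonomy_nodes.tsv`,
#' `taxonomy_subjects.tsv`), sample metadata (`metadata.tsv`), the truth
#' files (`truth_counts.tsv`, `truth_reads.tsv`) and the generating
#' configuration (`config.yaml`).
#'
#' @param fixture output of [simulate_fixture()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_taxonomy(fixture$tree, file.path(dir, "taxonomy_nodes.tsv"),
                 file.path(dir, "taxonomy_subjects.tsv"))
  md <- fixture$model$metadata
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in md$sample_id) {
    vh <- fixture$hits$viral_hits
    vh <- vh[sub("_[rb][0-9]+$", "", vh$query_id) == s, , drop = FALSE]
    write_hit_table(vh, file.path(dir, paste0("viral_hits_", s, ".tsv")))
    bh <- fixture$hits$bacterial_hits
    bh <- bh[sub("_[rb][0-9]+$", "", bh$query_id) == s, , drop = FALSE]
    write_hit_table(bh, file.path(dir, paste0("bacterial_hits_", s, ".tsv")))
  }
  tc <- data.frame(taxon_id = rownames(fixture$community$counts),
                   fixture$community$counts, check.names = FALSE)
  utils::write.table(tc, file.path(dir, "truth_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$hits$read_truth,
                     file.path(dir, "truth_reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- list(n_samples = fixture$model$n_samples,
              reads_per_sample = fixture$model$reads_per_sample,
              depth_sdlog = fixture$model$depth_sdlog,
              bacterial_only_per_sample =
                fixture$model$bacterial_only_per_sample,
              class_read_shares =
                as.list(fixture$model$class_read_shares),
              p_bacterial_homology =
                as.list(fixture$model$p_bacterial_homology),
              noise = fixture$model$noise,
              seed = fixture$model$seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write hits in 13-column BLAST tabular layout (outfmt 6 + qlen)
#' @param hits hit data.frame in [read_hit_table()] layout.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c(BLAST6_COLS, "query_length")
  utils::write.table(hits[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
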