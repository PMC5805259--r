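# Synthetic fixture generator: taxonomy, community, hit tables,
# fixture round trips.

test_that("simulated taxonomy has the expected node and subject counts", {
  tr <- simulate_taxonomy(3, 2, n_orders = 2, seed = 1)
  expect_equal(sum(tr$nodes$rank == "family"), 3L)
  expect_equal(sum(tr$nodes$rank == "species"), 6L)
  expect_equal(sum(tr$nodes$rank == "order"), 2L)
  expect_equal(nrow(tr$subjects), 6L)
})

test_that("a pure-prophage class mix tags every subject prophage", {
  tr <- simulate_taxonomy(4, 3, class_mix = c(prophage = 1,
                                              bacteriophage = 0,
                                              eukaryotic_virus = 0),
                          seed = 2)
  expect_true(all(tr$subjects$viral_class == "prophage"))
})

test_that("the same seed reproduces the same taxonomy and fixture", {
  a <- simulate_taxonomy(5, 3, seed = 9)
  b <- simulate_taxonomy(5, 3, seed = 9)
  expect_identical(a, b)
  f1 <- small_fixture(seed = 4L, n_samples = 4, reads_per_sample = 80)
  f2 <- small_fixture(seed = 4L, n_samples = 4, reads_per_sample = 80)
  expect_identical(f1$hits$viral_hits, f2$hits$viral_hits)
  expect_identical(f1$community$counts, f2$community$counts)
})

test_that("prevalence probability 1 and 0 behave deterministically", {
  tr <- simulate_taxonomy(2, 2, seed = 3)
  m <- community_model(tr, n_samples = 10, reads_per_sample = 100,
                       bacterial_only_per_sample = 0, seed = 3)
  m$taxa$prevalence_prob <- c(1, 1, 0, 0)
  cm <- simulate_community(m, seed = 4)
  expect_true(all(cm$presence[1:2, ] == 1L))
  expect_true(all(cm$presence[3:4, ] == 0L))
  expect_true(all(cm$counts[3:4, ] == 0L))
})

test_that("mean occurrences match the binomial expectation", {
  tr <- simulate_taxonomy(1, 1, class_mix = c(prophage = 1,
                                              bacteriophage = 0,
                                              eukaryotic_virus = 0),
                          seed = 5)
  m <- community_model(tr, n_samples = 72, reads_per_sample = 10,
                       bacterial_only_per_sample = 0, seed = 5)
  m$taxa$prevalence_prob <- 0.9
  occ <- vapply(seq_len(1000), function(s) {
    sum(simulate_community(m, seed = s)$presence[1, ])
  }, 1)
  se <- sqrt(72 * 0.9 * 0.1 / 1000)
  expect_lt(abs(mean(occ) - 64.8), 3 * se)
})

test_that("the noiseless limit is recovered exactly at species level", {
  fx <- small_fixture(seed = 6L, n_samples = 6, reads_per_sample = 150,
                      noise = list(identity_mean = 95, identity_sd = 0,
                                   coverage_shape1 = 9000,
                                   coverage_shape2 = 1000,
                                   fail_rate = 0, off_target_rate = 0))
  res <- assign_fixture(fx)
  truth <- fx$hits$read_truth
  expect_equal(nrow(res$assignments), nrow(truth))
  m <- merge(truth, res$assignments, by = "query_id")
  expect_true(all(m$taxon_id.x == m$taxon_id.y))
  expect_true(all(m$resolution_rank == "species"))
})

test_that("off-target ties and only them fall to the family rank", {
  fx <- small_fixture(seed = 7L, n_samples = 6, reads_per_sample = 200,
                      noise = list(identity_mean = 95, identity_sd = 2,
                                   coverage_shape1 = 9000,
                                   coverage_shape2 = 1000,
                                   fail_rate = 0, off_target_rate = 0.1))
  res <- assign_fixture(fx)
  m <- merge(fx$hits$read_truth, res$assignments, by = "query_id")
  expect_true(all(m$resolution_rank[m$off_target] == "family"))
  expect_true(all(m$resolution_rank[!m$off_target] == "species"))
})

test_that("bacterial homology skews the dual pool towards prophages", {
  fx <- small_fixture(
    seed = 8L, n_samples = 8, reads_per_sample = 500,
    p_bacterial_homology = c(prophage = 0.95, bacteriophage = 0.3,
                             eukaryotic_virus = 0.02))
  res <- assign_fixture(fx)
  ps <- partition_summary(res$assignments)
  truth <- fx$hits$read_truth[fx$hits$read_truth$passes_filter, ]
  # binomial check against the generator parameters, per class
  for (cl in c("prophage", "eukaryotic_virus")) {
    sel <- truth$viral_class == cl
    p <- c(prophage = 0.95, bacteriophage = 0.3,
           eukaryotic_virus = 0.02)[[cl]]
    se <- sqrt(p * (1 - p) / sum(sel))
    expect_lt(abs(mean(truth$has_bacterial[sel]) - p), 3 * se + 1e-9)
  }
  expect_gt(ps$proportions["virus_and_bacteria", "prophage"],
            ps$proportions["virus_only", "prophage"])
})

test_that("truth accounting matches the hit tables when off-target is 0", {
  fx <- small_fixture(seed = 9L, n_samples = 4, reads_per_sample = 100,
                      noise = list(identity_mean = 95, identity_sd = 4,
                                   coverage_shape1 = 18,
                                   coverage_shape2 = 2,
                                   fail_rate = 0.02, off_target_rate = 0))
  expect_equal(nrow(fx$hits$read_truth),
               length(unique(fx$hits$viral_hits$query_id)))
  expect_equal(nrow(fx$hits$read_truth), sum(fx$community$counts))
})

test_that("fixtures round-trip through the on-disk layout", {
  fx <- small_fixture(seed = 10L, n_samples = 3, reads_per_sample = 60)
  dir <- withr::local_tempdir()
  write_fixture(fx, dir)
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(md$sample_id, fx$model$metadata$sample_id)
  tree <- read_taxonomy(file.path(dir, "taxonomy_nodes.tsv"),
                        file.path(dir, "taxonomy_subjects.tsv"))
  expect_equal(tree$nodes, fx$tree$nodes)
  vh <- read_hit_table(file.path(dir, "viral_hits_S01.tsv"), "viral")
  in_mem <- fx$hits$viral_hits
  in_mem <- in_mem[sub("_[rb][0-9]+$", "", in_mem$query_id) == "S01", ]
  expect_equal(nrow(vh), nrow(in_mem))
  expect_equal(sort(vh$query_id), sort(in_mem$query_id))
  expect_equal(vh$percent_identity[order(vh$query_id, vh$subject_id)],
               in_mem$percent_identity[order(in_mem$query_id,
                                             in_mem$subject_id)])
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$n_samples, 3L)
})

test_that("the packaged default fixture parses and assigns end to end", {
  dir <- system.file("extdata", "default_fixture", package = "oralvirome")
  md <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  tree <- read_taxonomy(file.path(dir, "taxonomy_nodes.tsv"),
                        file.path(dir, "taxonomy_subjects.tsv"))
  expect_equal(nrow(md), 5L)
  per <- lapply(md$sample_id, function(s) {
    vh <- read_hit_table(file.path(dir, paste0("viral_hits_", s, ".tsv")),
                         "viral")
    bh <- read_hit_table(file.path(dir,
                                   paste0("bacterial_hits_", s, ".tsv")),
                         "bacterial")
    assign_all(vh, bh, tree, sample_id = s)
  })
  asg <- do.call(rbind, lapply(per, `[[`, "assignments"))
  expect_gt(nrow(asg), 100)
  tt <- build_taxon_table(asg, tree, metadata = md)
  expect_equal(sum(tt$counts), nrow(asg))
})

test_that("two same-seed fixture writes are byte-identical", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(small_fixture(seed = 12L, n_samples = 3,
                              reads_per_sample = 50), d1)
  write_fixture(small_fixture(seed = 12L, n_samples = 3,
                              reads_per_sample = 50), d2)
  for (f in c("viral_hits_S01.tsv", "bacterial_hits_S02.tsv",
              "taxonomy_nodes.tsv", "truth_counts.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
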