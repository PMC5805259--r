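# Hit filtering thresholds and best-hit / LCA read assignment.

test_that("filter thresholds are inclusive except the e-value bound", {
  thr <- filter_thresholds()
  # exactly at the identity and coverage bounds: retained
  h <- mk_hit("q", "ref1", percent_identity = 80.0,
              alignment_length = 75L, query_length = 100L, e_value = 1e-4)
  expect_equal(nrow(filter_hits(h, thr)), 1L)
  # identity just below the bound: removed
  h2 <- mk_hit("q", "ref1", percent_identity = 79.9,
               alignment_length = 75L, query_length = 100L, e_value = 1e-4)
  expect_equal(nrow(filter_hits(h2, thr)), 0L)
  # e-value exactly at the bound: removed (strict <)
  h3 <- mk_hit("q", "ref1", percent_identity = 90,
               alignment_length = 80L, query_length = 100L, e_value = 1e-3)
  expect_equal(nrow(filter_hits(h3, thr)), 0L)
  # coverage just below 75%: removed
  h4 <- mk_hit("q", "ref1", percent_identity = 90,
               alignment_length = 74L, query_length = 100L, e_value = 1e-4)
  expect_equal(nrow(filter_hits(h4, thr)), 0L)
})

test_that("filtering equals a brute-force row scan and is idempotent", {
  set.seed(101)
  n <- 200
  hits <- mk_hit(paste0("q", 1:n), "ref1",
                 percent_identity = runif(n, 60, 100),
                 alignment_length = sample(40:200, n, TRUE),
                 query_length = sample(100:250, n, TRUE),
                 e_value = 10^runif(n, -12, 0))
  thr <- filter_thresholds()
  got <- filter_hits(hits, thr)
  keep <- logical(n)
  for (i in seq_len(n)) {   # brute force, one row at a time
    keep[i] <- hits$e_value[i] < 1e-3 &&
      hits$percent_identity[i] >= 80 &&
      hits$alignment_length[i] / hits$query_length[i] >= 0.75
  }
  expect_equal(got, hits[keep, ])
  expect_equal(filter_hits(got, thr), got)
})

test_that("a single passing hit is assigned at species", {
  tree <- toy_taxonomy()
  a <- assign_read(mk_hit("q1", "ref1"), tree)
  expect_equal(a$taxon_id, "s1")
  expect_equal(a$resolution_rank, "species")
  expect_equal(a$co_optimal_count, 1L)
  expect_equal(a$viral_class, "prophage")
})

test_that("co-optimal hits to sibling species resolve to their genus", {
  tree <- toy_taxonomy()
  hits <- mk_hits(mk_hit("q1", "ref1"), mk_hit("q1", "ref2"))
  a <- assign_read(hits, tree)
  expect_equal(a$taxon_id, "g1")       # manual path intersection
  expect_equal(a$resolution_rank, "genus")
  expect_equal(a$co_optimal_count, 2L)
})

test_that("cross-genus and cross-family ties climb the tree", {
  tree <- toy_taxonomy()
  # s1 (g1) and s3 (g2) share family f1
  a <- assign_read(mk_hits(mk_hit("q", "ref1"), mk_hit("q", "ref3")), tree)
  expect_equal(a$taxon_id, "f1")
  # s1 (f1) and s4 (f2) share only the order
  b <- assign_read(mk_hits(mk_hit("q", "ref1"), mk_hit("q", "ref4")), tree)
  expect_equal(b$taxon_id, "o1")
})

test_that("co-optimal hits in disjoint trees are UNDETERMINED", {
  tree <- toy_taxonomy()
  a <- assign_read(mk_hits(mk_hit("q", "ref1"), mk_hit("q", "ref5")), tree)
  expect_equal(a$taxon_id, UNDETERMINED)
  expect_true(is.na(a$resolution_rank))
})

test_that("ranking prefers identity, then length, then bit score", {
  tree <- toy_taxonomy()
  hits <- mk_hits(
    mk_hit("q", "ref1", percent_identity = 96, alignment_length = 150L),
    mk_hit("q", "ref2", percent_identity = 95, alignment_length = 180L))
  expect_equal(assign_read(hits, tree)$taxon_id, "s1")
  hits2 <- mk_hits(
    mk_hit("q", "ref1", percent_identity = 95, alignment_length = 150L),
    mk_hit("q", "ref2", percent_identity = 95, alignment_length = 160L))
  expect_equal(assign_read(hits2, tree)$taxon_id, "s2")
  hits3 <- mk_hits(
    mk_hit("q", "ref1", bit_score = 250), mk_hit("q", "ref2",
                                                 bit_score = 260))
  # equal identity and length: LCA despite the bit-score difference
  expect_equal(assign_read(hits3, tree)$taxon_id, "g1")
})

test_that("duplicate hits to one subject collapse to the best", {
  tree <- toy_taxonomy()
  hits <- mk_hits(
    mk_hit("q", "ref1", percent_identity = 90),
    mk_hit("q", "ref1", percent_identity = 96))
  a <- assign_read(hits, tree)
  expect_equal(a$taxon_id, "s1")
  expect_equal(a$co_optimal_count, 1L)
})

test_that("LCA assignment matches a descendant-set oracle on random trees", {
  set.seed(77)
  for (rep in 1:200) {
    tree <- random_taxonomy()
    sp <- tree$subjects$taxon_id
    k <- sample(1:min(4, length(sp)), 1)
    pick <- sample(sp, k)
    got <- tax_lca(tree, pick)
    want <- oracle_lca(tree, pick)
    expect_identical(got, want)
  }
})

test_that("shrinking tie_margin never coarsens an assignment", {
  set.seed(88)
  tree <- toy_taxonomy()
  depth_of <- function(a) {
    if (a$taxon_id == UNDETERMINED) 0L
    else match(a$resolution_rank, TAXONOMY_RANKS)
  }
  for (rep in 1:50) {
    n <- sample(2:4, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_hit("q", sample(paste0("ref", 1:5), 1),
             percent_identity = round(runif(1, 90, 100), 1),
             alignment_length = sample(140:160, 1))
    }))
    margins <- c(0, 2, 5, 20)
    depths <- vapply(margins, function(m) {
      depth_of(assign_read(hits, tree, tie_margin = m))
    }, 1L)
    # wider margin -> same or shallower (never deeper) resolution
    expect_true(all(diff(depths) <= 0))
  }
})

test_that("assign_all books viral and bacterial homology separately", {
  tree <- toy_taxonomy()
  viral <- mk_hits(mk_hit("q1", "ref1"), mk_hit("q2", "ref2"),
                   mk_hit("q3", "ref4"))
  bact <- mk_hits(mk_hit("q2", "bact1", db_label = "bacterial"),
                  mk_hit("q9", "bact2", db_label = "bacterial"),
                  mk_hit("q10", "bact2", db_label = "bacterial"))
  res <- assign_all(viral, bact, tree, sample_id = "S1")
  expect_equal(nrow(res$assignments), 3L)
  expect_equal(sum(res$assignments$bacterial_hit), 1L)
  expect_equal(res$assignments$bacterial_hit[
    res$assignments$query_id == "q2"], TRUE)
  # q9/q10 have bacterial homology only: counted, not assigned
  expect_equal(res$n_bacterial_only, 2L)
  expect_true(all(res$assignments$viral_hit))
})

test_that("assignment recovers generator truth for unambiguous reads", {
  fx <- small_fixture(seed = 5L)
  res <- assign_fixture(fx)
  truth <- fx$hits$read_truth
  # unambiguous = primary hit passes filters and no off-target tie
  unamb <- truth[truth$passes_filter & !truth$off_target, ]
  m <- merge(unamb, res$assignments, by = "query_id")
  expect_equal(nrow(m), nrow(unamb))
  expect_gte(mean(m$taxon_id.x == m$taxon_id.y), 0.95)
  # off-target ties resolve to the family of the true species
  ties <- truth[truth$passes_filter & truth$off_target, ]
  if (nrow(ties)) {
    mt <- merge(ties, res$assignments, by = "query_id")
    fam <- vapply(mt$taxon_id.x, function(id)
      tax_ancestor_at_rank(fx$tree, id, "family"), character(1))
    expect_true(all(mt$resolution_rank == "family"))
    expect_equal(unname(fam), mt$taxon_id.y)
  }
})
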