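# Hand-built fixtures shared across tests.

# Small taxonomy with two disjoint order trees, a genus-less family, and
# classed subjects at every species.
toy_taxonomy <- function() {
  nodes <- data.frame(
    taxon_id  = c("o1", "f1", "g1", "s1", "s2", "g2", "s3",
                  "f2", "s4", "o2", "f3", "g3", "s5"),
    name      = c("OrderA", "FamA", "GenA", "SpA1", "SpA2", "GenB", "SpB1",
                  "FamB", "SpC1", "OrderB", "FamC", "GenC", "SpD1"),
    rank      = c("order", "family", "genus", "species", "species",
                  "genus", "species", "family", "species", "order",
                  "family", "genus", "species"),
    parent_id = c(NA, "o1", "f1", "g1", "g1", "f1", "g2",
                  "o1", "f2", NA, "o2", "f3", "g3"),
    stringsAsFactors = FALSE)
  subjects <- data.frame(
    subject_id = paste0("ref", 1:5),
    taxon_id = c("s1", "s2", "s3", "s4", "s5"),
    viral_class = c("prophage", "bacteriophage", "bacteriophage",
                    "eukaryotic_virus", "prophage"),
    stringsAsFactors = FALSE)
  virome_taxonomy(nodes, subjects)
}

mk_hit <- function(query_id, subject_id, percent_identity = 95,
                   alignment_length = 150L, query_length = 200L,
                   e_value = 1e-10, bit_score = 250,
                   db_label = "viral") {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = percent_identity,
             alignment_length = as.integer(alignment_length),
             mismatches = 0L, gap_openings = 0L, q_start = 1L,
             q_end = as.integer(alignment_length), s_start = 1L,
             s_end = as.integer(alignment_length), e_value = e_value,
             bit_score = bit_score, query_length = as.integer(query_length),
             db_label = db_label, stringsAsFactors = FALSE)
}

mk_hits <- function(...) do.call(rbind, list(...))

# Random rank-labelled forest for oracle tests: every family under an
# order; genera optionally skipped; species under a genus or family.
random_taxonomy <- function(n_nodes_max = 50) {
  n_ord <- sample(1:3, 1)
  nodes <- data.frame(taxon_id = paste0("O", seq_len(n_ord)),
                      name = paste0("O", seq_len(n_ord)), rank = "order",
                      parent_id = NA_character_, stringsAsFactors = FALSE)
  n_fam <- sample(1:6, 1)
  for (i in seq_len(n_fam)) {
    nodes <- rbind(nodes, data.frame(
      taxon_id = paste0("F", i), name = paste0("F", i), rank = "family",
      parent_id = sample(nodes$taxon_id[nodes$rank == "order"], 1)))
  }
  n_gen <- sample(0:6, 1)
  for (i in seq_len(n_gen)) {
    nodes <- rbind(nodes, data.frame(
      taxon_id = paste0("G", i), name = paste0("G", i), rank = "genus",
      parent_id = sample(nodes$taxon_id[nodes$rank == "family"], 1)))
  }
  n_sp <- sample(2:min(20, n_nodes_max - nrow(nodes)), 1)
  parents <- nodes$taxon_id[nodes$rank %in% c("family", "genus")]
  for (i in seq_len(n_sp)) {
    nodes <- rbind(nodes, data.frame(
      taxon_id = paste0("S", i), name = paste0("S", i), rank = "species",
      parent_id = sample(parents, 1)))
  }
  sp <- nodes$taxon_id[nodes$rank == "species"]
  subjects <- data.frame(subject_id = paste0("ref_", sp), taxon_id = sp,
                         viral_class = sample(VIRAL_CLASSES, length(sp),
                                              replace = TRUE),
                         stringsAsFactors = FALSE)
  virome_taxonomy(nodes, subjects)
}

# Independent LCA oracle: for every node, collect its descendant-or-self
# set by scanning parent links; the LCA is the deepest node whose set
# covers all query taxa.
oracle_lca <- function(tree, taxon_ids) {
  nodes <- tree$nodes
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  covers <- function(node) {
    all(vapply(taxon_ids, function(t) {
      cur <- t
      while (!is.na(cur)) {
        if (cur == node) return(TRUE)
        cur <- parent[[cur]]
      }
      FALSE
    }, NA))
  }
  cand <- nodes$taxon_id[vapply(nodes$taxon_id, covers, NA)]
  if (!length(cand)) return(NA_character_)
  depth <- match(nodes$rank[match(cand, nodes$taxon_id)],
                 c("order", "family", "genus", "species"))
  cand[which.max(depth)]
}

# Small fixture used by several suites (kept cheap).
small_fixture <- function(seed = 11L, n_samples = 12,
                          reads_per_sample = 420, ...) {
  simulate_fixture(n_samples = n_samples,
                   reads_per_sample = reads_per_sample,
                   bacterial_only_per_sample = 60,
                   n_families = 10, species_per_family = 4,
                   seed = seed, ...)
}

# Run assignment over every sample of a fixture.
assign_fixture <- function(fx, tie_margin = 0) {
  vh <- fx$hits$viral_hits
  bh <- fx$hits$bacterial_hits
  vh_s <- sub("_[rb][0-9]+$", "", vh$query_id)
  bh_s <- sub("_[rb][0-9]+$", "", bh$query_id)
  per <- lapply(fx$model$metadata$sample_id, function(s) {
    assign_all(vh[vh_s == s, , drop = FALSE],
               bh[bh_s == s, , drop = FALSE],
               fx$tree, tie_margin = tie_margin, sample_id = s)
  })
  list(assignments = do.call(rbind, lapply(per, `[[`, "assignments")),
       n_bacterial_only = sum(vapply(per, `[[`, 0, "n_bacterial_only")))
}
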