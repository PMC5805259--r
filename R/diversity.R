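# Alpha diversity (Shannon, log base 2) with Monte Carlo permutation
# t-tests and Benjamini-Hochberg correction; beta diversity (Bray-Curtis)
# with within/between-group distance comparisons and Bonferroni
# correction.

#' Shannon diversity index (bits)
#'
#' `H = -sum(p_i * log2(p_i))` over the positive proportions
#' `p_i = count_i / total`. Log base 2 throughout, so the value is bounded
#' by `log2` of the number of taxa.
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry.
#' @return Shannon index in bits.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("shannon: negative counts")
  if (sum(counts) == 0) stop("shannon: all-zero count vector is undefined")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Per-sample Shannon alpha diversity of a taxon table
#'
#' @param table a [taxon_table()].
#' @return named numeric vector, one Shannon value (bits) per sample;
#'   all-zero samples get `NA`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  apply(table$counts, 2, function(x) {
    if (sum(x) == 0) NA_real_ else shannon(x)
  })
}

#' Bray-Curtis dissimilarity matrix of a taxon table
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, computed with
#' `vegan::vegdist`. Pairs of all-zero samples have undefined
#' dissimilarity; they are returned as `NA` and listed in the
#' `"undefined_pairs"` attribute.
#'
#' @param table a [taxon_table()] with at least two samples.
#' @return symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]` (or `NA` for undefined pairs).
#' @export
bray_curtis_matrix <- function(table) {
  stopifnot(inherits(table, "taxon_table"), ncol(table$counts) >= 2)
  d <- suppressWarnings(vegan::vegdist(t(table$counts), method = "bray"))
  m <- as.matrix(d)
  und <- which(is.nan(m) & upper.tri(m), arr.ind = TRUE)
  m[is.nan(m)] <- NA_real_
  attr(m, "undefined_pairs") <-
    if (nrow(und)) data.frame(a = rownames(m)[und[, 1]],
                              b = colnames(m)[und[, 2]]) else NULL
  m
}

# Welch t statistic; zero-variance guard: equal means -> 0, else +-Inf.
.t_stat <- function(x, y) {
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  d <- mean(x) - mean(y)
  if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / se
  }
}

# Two-tailed Monte Carlo permutation t-test on two value sets. The p-value
# uses the add-one estimator (1 + #extreme) / (1 + n_perm), so it is never
# zero. The pooled values are sorted and the smaller group size is drawn,
# so the result is exactly invariant to swapping the two group labels
# under a fixed seed. Returns observed t and p_raw.
.perm_t_test <- function(x, y, n_permutations) {
  obs <- .t_stat(x, y)
  pool <- sort(c(x, y))
  n <- length(pool)
  m <- min(length(x), length(y))
  extreme <- 0L
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(n, m)
    t_i <- .t_stat(pool[idx], pool[-idx])
    if (abs(t_i) >= abs(obs)) extreme <- extreme + 1L
  }
  list(observed_t = obs,
       p_raw = (1 + extreme) / (1 + n_permutations))
}

#' Compare alpha diversity between groups (permutation t-test + FDR)
#'
#' Two-tailed nonparametric t-test: the observed Welch t statistic is
#' compared against its distribution under random reassignment of group
#' labels. Raw p-values over all pairwise group comparisons are adjusted
#' with Benjamini-Hochberg FDR.
#'
#' @param alpha named numeric vector of per-sample diversity values.
#' @param groups factor/character of group labels (e.g. sex F/M), aligned
#'   with `alpha` (or named by sample).
#' @param n_permutations Monte Carlo permutations (default 999, min 99).
#' @param seed integer seed for the permutations.
#' @return data.frame with `group_a`, `group_b`, `n_a`, `n_b`,
#'   `observed_t`, `p_raw`, `p_adjusted`, `n_permutations`, `seed`.
#' @export
compare_alpha <- function(alpha, groups, n_permutations = 999, seed = 1L) {
  stopifnot(n_permutations >= 99)
  if (!is.null(names(groups)) && !is.null(names(alpha))) {
    groups <- groups[names(alpha)]
  }
  keep <- !is.na(alpha) & !is.na(groups)
  alpha <- alpha[keep]
  groups <- as.character(groups)[keep]
  lev <- sort(unique(groups))
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  set.seed(seed)
  rows <- lapply(pairs, function(pr) {
    x <- alpha[groups == pr[1]]
    y <- alpha[groups == pr[2]]
    r <- .perm_t_test(x, y, n_permutations)
    data.frame(group_a = pr[1], group_b = pr[2],
               n_a = length(x), n_b = length(y),
               observed_t = r$observed_t, p_raw = r$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- fdr_bh(out$p_raw)
  out$n_permutations <- n_permutations
  out$seed <- seed
  out
}

#' Compare Bray-Curtis distances within and between groups
#'
#' Splits the pairwise distances into within-group sets (one per group)
#' and between-group sets (one per group pair), summarises each with
#' five-number boxplot statistics, and compares every pair of distance
#' sets with a two-tailed Monte Carlo permutation t-test. Raw p-values are
#' Bonferroni-corrected by the number of comparisons (capped at 1).
#'
#' @param dm symmetric distance matrix from [bray_curtis_matrix()].
#' @param groups group labels named by sample (or aligned with the matrix
#'   order).
#' @param n_permutations Monte Carlo permutations (default 999, min 99).
#' @param seed integer seed.
#' @return list with `set_stats` (per distance set: n, min, Q1, median,
#'   Q3, max) and `comparisons` (set_a, set_b, observed_t, p_raw,
#'   p_bonferroni, n_permutations, seed); comparisons involving an empty
#'   set are skipped with a message.
#' @export
compare_beta <- function(dm, groups, n_permutations = 999, seed = 1L) {
  stopifnot(n_permutations >= 99, is.matrix(dm),
            nrow(dm) == ncol(dm))
  ids <- rownames(dm)
  if (!is.null(names(groups))) groups <- groups[ids]
  groups <- as.character(groups)
  lev <- sort(unique(groups))

  sets <- list()
  for (g in lev) {
    idx <- which(groups == g)
    if (length(idx) >= 2) {
      sub <- dm[idx, idx, drop = FALSE]
      sets[[paste0("within_", g)]] <- sub[upper.tri(sub)]
    } else {
      sets[[paste0("within_", g)]] <- numeric(0)
      message("group ", g, " has a single sample; its within-group ",
              "distance set is empty")
    }
  }
  if (length(lev) >= 2) {
    for (pr in utils::combn(lev, 2, simplify = FALSE)) {
      ia <- which(groups == pr[1]); ib <- which(groups == pr[2])
      sets[[paste0("between_", pr[1], "_", pr[2])]] <-
        as.vector(dm[ia, ib, drop = FALSE])
    }
  }
  sets <- lapply(sets, function(v) v[!is.na(v)])

  set_stats <- do.call(rbind, lapply(names(sets), function(nm) {
    v <- sets[[nm]]
    fv <- if (length(v)) stats::fivenum(v) else rep(NA_real_, 5)
    data.frame(set = nm, n = length(v), min = fv[1], q1 = fv[2],
               median = fv[3], q3 = fv[4], max = fv[5],
               stringsAsFactors = FALSE)
  }))

  prs <- utils::combn(names(sets), 2, simplify = FALSE)
  prs <- Filter(function(pr) length(sets[[pr[1]]]) >= 2 &&
                  length(sets[[pr[2]]]) >= 2, prs)
  set.seed(seed)
  comps <- do.call(rbind, lapply(prs, function(pr) {
    r <- .perm_t_test(sets[[pr[1]]], sets[[pr[2]]], n_permutations)
    data.frame(set_a = pr[1], set_b = pr[2], observed_t = r$observed_t,
               p_raw = r$p_raw, stringsAsFactors = FALSE)
  }))
  if (!is.null(comps)) {
    comps$p_bonferroni <- pmin(comps$p_raw * nrow(comps), 1)
    comps$n_permutations <- n_permutations
    comps$seed <- seed
  }
  list(set_stats = set_stats, comparisons = comps)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control; adjusted values are monotone in
#' the ranked raw values and never smaller than them.
#'
#' @param p_values numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values in input order.
#' @export
fdr_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("fdr_bh: p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
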