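# Nested (cells-within-animals) bootstrap group comparison, Bonferroni
# correction, and the behavioral discrimination index.

#' Build a nested sample
#'
#' @param values List of numeric vectors, one per animal (cell-level metric
#'   values), or a data frame with columns `animal` and `value`.
#' @param condition Condition label.
#' @return A `dg_nested_sample`.
#' @export
nested_sample <- function(values, condition = "") {
  if (is.data.frame(values)) {
    values <- split(values$value, values$animal)
  }
  values <- lapply(values, as.numeric)
  if (length(values) < 1 || any(vapply(values, length, integer(1)) < 1))
    stop("invalid input: need >= 1 animal with >= 1 value each", call. = FALSE)
  structure(list(values = values, condition = condition),
            class = "dg_nested_sample")
}

#' Nested two-level bootstrap test for pooled-cell group comparisons
#'
#' When cell-level metrics from several animals are pooled per condition,
#' cells are not independent samples; this test builds the null by combining
#' the animals of both conditions into one pool and, for each bootstrap
#' replicate and condition, resampling animals with replacement from the
#' pool and then one value from each sampled animal, for as many draws as
#' the condition's original cell count. The replicate statistic is the
#' difference of the two pseudo-condition means; the two-sided p-value is
#' the fraction of replicates at least as extreme as the observed difference
#' of condition means, with a continuity floor of `1 / (n_boot + 1)` so p is
#' never exactly 0. `pool = "within"` resamples animals within each
#' condition instead (sensitivity variant).
#'
#' @param a,b `dg_nested_sample`s (or inputs accepted by [nested_sample()]).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param pool Null construction: animals resampled from the combined pool
#'   (default) or within condition.
#' @param return_null Keep the replicate-level null differences for audit.
#' @return A list: `p` (two-sided), `observed` (mean(a) - mean(b)), `n_boot`,
#'   `seed`, and optionally `null` (replicate differences).
#' @export
nested_bootstrap_test <- function(a, b, n_boot = 100000L, seed = 1L,
                                  pool = c("combined", "within"),
                                  return_null = FALSE) {
  pool <- match.arg(pool)
  if (!inherits(a, "dg_nested_sample")) a <- nested_sample(a)
  if (!inherits(b, "dg_nested_sample")) b <- nested_sample(b)
  if (n_boot < 100) stop("n_boot < 100 is refused as unstable", call. = FALSE)

  va <- a$values; vb <- b$values
  na <- sum(lengths(va)); nb <- sum(lengths(vb))
  observed <- mean(unlist(va)) - mean(unlist(vb))

  boot_means <- function(animals, cluster_sizes, n_rep) {
    # one pseudo-condition mean per replicate: for each animal slot of the
    # condition, draw an animal with replacement from the pool, then that
    # slot's original number of values with replacement within the sampled
    # animal. Keeping the cluster structure in the null is what makes the
    # test respect the nesting.
    flat <- unlist(animals, use.names = FALSE)
    lens <- lengths(animals)
    offs <- c(0L, cumsum(lens))[seq_along(lens)]
    K <- length(animals)
    tot <- numeric(n_rep)
    for (m_k in cluster_sizes) {
      ai <- sample.int(K, n_rep, replace = TRUE)
      ai_rep <- rep(ai, each = m_k)
      vi <- offs[ai_rep] + ceiling(stats::runif(n_rep * m_k) * lens[ai_rep])
      tot <- tot + colSums(matrix(flat[vi], m_k, n_rep))
    }
    tot / sum(cluster_sizes)
  }

  null_diff <- with_stream(seed, "nested_bootstrap", {
    if (pool == "combined") {
      pooled <- c(va, vb)
      boot_means(pooled, lengths(va), n_boot) - boot_means(pooled, lengths(vb), n_boot)
    } else {
      boot_means(va, lengths(va), n_boot) - boot_means(vb, lengths(vb), n_boot)
    }
  })
  p <- (1 + sum(abs(null_diff) >= abs(observed))) / (n_boot + 1)
  res <- list(p = p, observed = observed, n_boot = n_boot, seed = seed, pool = pool)
  if (return_null) res$null <- null_diff
  res
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("invalid input: p must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p)
}

#' Contextual discrimination index
#'
#' `DI = (a - b) / (a + b)` for freezing times (or percentages) in the
#' shocked context `a` and the novel context `b`; 0 means no discrimination,
#' 1 freezing only in the shocked context.
#'
#' @param freeze_a,freeze_b Nonnegative freezing measures.
#' @return DI in `[-1, 1]`.
#' @export
discrimination_index <- function(freeze_a, freeze_b) {
  if (any(freeze_a < 0 | freeze_b < 0))
    stop("invalid input: freezing measures must be nonnegative", call. = FALSE)
  if (any(freeze_a + freeze_b == 0))
    stop("undefined DI: both freezing measures are zero", call. = FALSE)
  (freeze_a - freeze_b) / (freeze_a + freeze_b)
}
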