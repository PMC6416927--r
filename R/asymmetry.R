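# Asymmetry of ancestral-state inheritance between the two copies of a
# duplicate pair. For a pair with n partitioned items (exactly one copy
# retains the ancestral state) of which copy A retains k_A, the shares are
# F_A = k_A / n and F_B = 1 - F_A, and the asymmetry score is
#   Y = max(F_A, F_B) - (1 - max(F_A, F_B)) = |2 F_A - 1|,
# ranging from 0 (even split) to 1 (one copy inherited everything). The
# copy with the larger share is designated the "ancestral" copy; exact ties
# are broken randomly with the run RNG.

#' Asymmetry score of a duplicate pair
#'
#' @param k_A Number of partitioned items retained by copy A.
#' @param n Total number of partitioned items for the pair.
#' @param min_partitioned Pairs with fewer partitioned items than this are
#'   rejected (default 5); scores from very few items are too granular to
#'   compare.
#' @return A one-row data frame: `n`, `k_A`, `F_A`, `Y`, and
#'   `ancestral_copy` (`"A"` or `"B"`, ties random).
#' @export
asymmetry_score <- function(k_A, n, min_partitioned = 5) {
  if (length(k_A) != 1 || length(n) != 1) stop("scalar k_A and n expected")
  if (k_A < 0 || k_A > n) stop("k_A must be in 0..n")
  if (n < min_partitioned) {
    stop("pair has n = ", n, " partitioned items, below the minimum of ",
         min_partitioned)
  }
  F_A <- k_A / n
  Y <- abs(2 * F_A - 1)
  anc <- if (k_A * 2 > n) "A" else if (k_A * 2 < n) "B" else
    sample(c("A", "B"), 1)
  data.frame(n = n, k_A = k_A, F_A = F_A, Y = Y, ancestral_copy = anc,
             stringsAsFactors = FALSE)
}

#' Asymmetry records for a table of duplicate pairs
#'
#' Vectorized version of [asymmetry_score()]: pairs below `min_partitioned`
#' are dropped (with a message), matching the usual filtering of pairs with
#' too few partitioned states.
#'
#' @param pair Pair identifiers.
#' @param k_A,n Per-pair partitioned counts as in [asymmetry_score()].
#' @inheritParams asymmetry_score
#' @return Data frame `pair`, `n`, `k_A`, `F_A`, `Y`, `ancestral_copy`.
#' @export
asymmetry_records <- function(pair, k_A, n, min_partitioned = 5) {
  keep <- n >= min_partitioned
  if (any(!keep)) {
    message("dropping ", sum(!keep), " pair(s) with fewer than ",
            min_partitioned, " partitioned items")
  }
  pair <- pair[keep]; k_A <- k_A[keep]; n <- n[keep]
  F_A <- k_A / n
  Y <- abs(2 * F_A - 1)
  anc <- ifelse(k_A * 2 > n, "A", ifelse(k_A * 2 < n, "B", NA))
  ties <- is.na(anc)
  if (any(ties)) anc[ties] <- sample(c("A", "B"), sum(ties), replace = TRUE)
  data.frame(pair = pair, n = n, k_A = k_A, F_A = F_A, Y = Y,
             ancestral_copy = anc, stringsAsFactors = FALSE)
}

#' Exact expected asymmetry under random partitioning
#'
#' If each of n partitioned items lands in either copy independently with
#' probability 1/2, k_A ~ Binomial(n, 1/2) and
#' E[Y | n] = E|2 k_A - n| / n, computed by enumeration.
#'
#' @param n Vector of partitioned-item counts.
#' @return Numeric vector of exact expectations, one per `n`.
#' @export
expected_asymmetry <- function(n) {
  vapply(n, function(ni) {
    k <- 0:ni
    sum(dbinom(k, ni, 0.5) * abs(2 * k - ni) / ni)
  }, numeric(1))
}

#' Grouped Bernoulli null for asymmetry scores
#'
#' The null keeps each pair's number of partitioned items n fixed and draws
#' which copy inherits each item by a fair coin: k_A ~ Binomial(n, 1/2).
#' Per replicate, a Y score is computed for every pair and averaged; the
#' distribution of replicate means is returned together with per-pair null
#' draws and the exact per-n expectation table.
#'
#' @param n_list Per-pair partitioned counts (all >= `min_partitioned`).
#' @param reps Number of replicates (default 1000).
#' @inheritParams asymmetry_score
#' @return Object of class `asymmetry_null`: `replicate_means` (length
#'   `reps`), `pair_draws` (reps x pairs matrix of null Y values), `exact`
#'   (data frame n, E_Y), `mean` (grand mean of the null draws).
#' @export
grouped_bernoulli_null <- function(n_list, reps = 1000, min_partitioned = 5) {
  if (!length(n_list)) stop("empty n_list")
  if (any(n_list < min_partitioned)) {
    stop("all pairs must have at least ", min_partitioned, " partitioned items")
  }
  npair <- length(n_list)
  k <- matrix(rbinom(reps * npair, rep(n_list, each = reps), 0.5),
              nrow = reps)
  Y <- abs(2 * k - matrix(n_list, reps, npair, byrow = TRUE)) /
    matrix(n_list, reps, npair, byrow = TRUE)
  uniq <- sort(unique(n_list))
  structure(list(
    replicate_means = rowMeans(Y),
    pair_draws = Y,
    n_list = n_list,
    exact = data.frame(n = uniq, E_Y = expected_asymmetry(uniq)),
    mean = mean(Y),
    reps = reps
  ), class = "asymmetry_null")
}

#' @export
print.asymmetry_null <- function(x, ...) {
  cat("Grouped Bernoulli null:", length(x$n_list), "pairs,",
      x$reps, "replicates\n")
  cat("  null mean Y:", format(x$mean, digits = 4),
      " (exact per-pair expectation:",
      format(mean(expected_asymmetry(x$n_list)), digits = 4), ")\n")
  invisible(x)
}

#' Compare observed asymmetry to its Bernoulli null
#'
#' Welch's two-sample t-test of the observed per-pair Y values against the
#' pooled per-pair null draws, plus a two-sample Kolmogorov-Smirnov
#' comparison of the distributions (used for the site-asymmetry path, whose
#' Y values are strongly discrete). When the observed scores are degenerate
#' (zero variance) only the KS comparison is reported.
#'
#' @param records Data frame from [asymmetry_records()].
#' @param null An `asymmetry_null` for the same pairs.
#' @return Object of class `asymmetry_test` with observed/null means, the
#'   Welch test, and the KS test.
#' @export
compare_to_null <- function(records, null) {
  if (nrow(records) < 2) stop("need at least 2 records")
  obs <- records$Y
  nulldraws <- as.vector(null$pair_draws)
  ks <- suppressWarnings(ks.test(obs, nulldraws))
  # degenerate observed scores are fine as long as the null side varies;
  # only a fully constant comparison falls back to KS alone
  welch <- tryCatch(t.test(obs, nulldraws, alternative = "two.sided"),
                    error = function(e) NULL)
  structure(list(
    observed_mean = mean(obs),
    null_mean = mean(nulldraws),
    n_pairs = nrow(records),
    welch = welch,
    p_welch = if (is.null(welch)) NA_real_ else welch$p.value,
    ks = ks,
    ks_statistic = unname(ks$statistic),
    p_ks = ks$p.value
  ), class = "asymmetry_test")
}

#' @export
print.asymmetry_test <- function(x, ...) {
  cat("Observed vs null asymmetry (", x$n_pairs, " pairs)\n", sep = "")
  cat("  mean Y observed:", format(x$observed_mean, digits = 4),
      " null:", format(x$null_mean, digits = 4), "\n")
  if (!is.null(x$welch)) {
    cat("  Welch t-test p:", format.pval(x$p_welch, digits = 4), "\n")
  }
  cat("  KS statistic:", format(x$ks_statistic, digits = 4),
      " p:", format.pval(x$p_ks, digits = 4), "\n")
  invisible(x)
}

#' Asymmetry recomputed on time-series subsets
#'
#' Time-series conditions within an experiment are correlated, which could
#' inflate apparent asymmetry. As a robustness check the per-pair scores are
#' recomputed using only the first, and only the last, element of each
#' series; pairs falling below `min_partitioned` within a subset are
#' dropped, and the surviving counts are reported.
#'
#' @param partition Data frame of partitioned items with columns `pair`,
#'   `item`, `copy` (`"A"`/`"B"`: which copy retained the ancestral state).
#' @param series Data frame with columns `item`, `series_id`, `position`
#'   (numeric order within the series). Items missing from `series` are
#'   kept in every subset (they are not part of any time series).
#' @inheritParams asymmetry_score
#' @return Data frame with one row per subset (`full`, `first`, `last`):
#'   `n_pairs`, `mean_Y`.
#' @export
timeseries_robustness_subsets <- function(partition, series,
                                          min_partitioned = 5) {
  need <- c("pair", "item", "copy")
  if (!all(need %in% names(partition))) {
    stop("partition needs columns: ", paste(need, collapse = ", "))
  }
  pick <- function(which_end) {
    if (is.null(series) || !nrow(series)) return(unique(partition$item))
    keepfun <- if (which_end == "first") which.min else which.max
    sel <- unlist(lapply(split(series, series$series_id), function(d) {
      d$item[keepfun(d$position)]
    }))
    c(setdiff(unique(partition$item), series$item), sel)
  }
  one_subset <- function(items) {
    d <- partition[partition$item %in% items, , drop = FALSE]
    if (!nrow(d)) return(c(n_pairs = 0, mean_Y = NA_real_))
    agg <- aggregate(cbind(n = copy == "A" | copy == "B",
                           k_A = copy == "A") ~ pair, data = d, FUN = sum)
    agg <- agg[agg$n >= min_partitioned, , drop = FALSE]
    if (!nrow(agg)) return(c(n_pairs = 0, mean_Y = NA_real_))
    Y <- abs(2 * agg$k_A / agg$n - 1)
    c(n_pairs = nrow(agg), mean_Y = mean(Y))
  }
  subsets <- list(full = unique(partition$item),
                  first = pick("first"), last = pick("last"))
  res <- t(vapply(subsets, one_subset, numeric(2)))
  data.frame(subset = rownames(res), n_pairs = res[, "n_pairs"],
             mean_Y = res[, "mean_Y"], row.names = NULL,
             stringsAsFactors = FALSE)
}
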