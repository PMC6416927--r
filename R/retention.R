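# Duplicate-retention odds per function group and the linear model relating
# group features to retention. The odds for group g after WGD event w is
#   R_gw = (D_gw / S_gw) / (D_!gw / S_!gw)
# where D counts WGD-duplicate genes (paralog retained) and S counts
# WGD-singletons (paralog lost), inside and outside the group. Confidence
# intervals are exact conditional (central Fisher) intervals for the 2x2
# table; the point estimate is always the sample odds ratio above, not the
# conditional MLE.

#' Retention odds of a function group
#'
#' @param D_g,S_g Duplicate and singleton counts inside the group.
#' @param D_ng,S_ng The same outside the group (complement).
#' @param conf_level Confidence level for the exact conditional interval.
#' @return One-row data frame: `R` (point estimate), `lower`, `upper`,
#'   `p.value` (Fisher's exact, two-sided). A zero singleton count yields an
#'   infinite estimate and a one-sided interval, with a warning.
#' @export
retention_odds <- function(D_g, S_g, D_ng, S_ng, conf_level = 0.95) {
  counts <- c(D_g, S_g, D_ng, S_ng)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be nonnegative")
  if (S_ng == 0 && D_ng == 0) stop("empty complement")
  if (S_g == 0 || S_ng == 0) {
    warning("zero singleton count: odds estimate is infinite/degenerate, ",
            "interval is one-sided")
  }
  R <- (D_g / S_g) / (D_ng / S_ng)
  tab <- matrix(c(D_g, S_g, D_ng, S_ng), 2, 2, byrow = TRUE)
  ci <- exact_or_ci(D_g, S_g, D_ng, S_ng, conf_level)
  ft <- fisher.test(tab)
  data.frame(R = R, lower = ci[1], upper = ci[2], p.value = ft$p.value)
}

#' Retention odds for a table of groups
#'
#' @param counts Data frame with columns `group`, `D`, `S` per group, plus
#'   genome totals derived from the table itself: the complement of each
#'   group is every other gene in the table's universe.
#' @param D_total,S_total Optional genome-wide totals; defaults to column
#'   sums of `counts` (i.e. the groups partition the annotated universe).
#' @inheritParams retention_odds
#' @return Data frame with one row per group: `group`, counts, `R`,
#'   `lower`, `upper`, `p.value`.
#' @export
retention_odds_table <- function(counts, D_total = NULL, S_total = NULL,
                                 conf_level = 0.95) {
  stopifnot(all(c("group", "D", "S") %in% names(counts)))
  if (is.null(D_total)) D_total <- sum(counts$D)
  if (is.null(S_total)) S_total <- sum(counts$S)
  res <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    retention_odds(counts$D[i], counts$S[i],
                   D_total - counts$D[i], S_total - counts$S[i],
                   conf_level = conf_level)
  }))
  cbind(counts[, c("group", "D", "S")], res)
}

#' Filter function groups by size and duplicate-pair support
#'
#' Groups must contain between `min_genes` and `max_genes` genes (inclusive)
#' and at least `min_pairs` WGD-duplicate pairs; odds from tiny or enormous
#' groups are either unstable or uninformative about function.
#'
#' @param groups Data frame with columns `group`, `gene_count`, `n_pairs`.
#' @param min_genes,max_genes,min_pairs Inclusive bounds (defaults 100,
#'   2000, 20).
#' @return The kept rows; removals are reported via `message()`.
#' @export
filter_groups <- function(groups, min_genes = 100, max_genes = 2000,
                          min_pairs = 20) {
  stopifnot(all(c("group", "gene_count", "n_pairs") %in% names(groups)))
  keep <- groups$gene_count >= min_genes & groups$gene_count <= max_genes &
    groups$n_pairs >= min_pairs
  if (any(!keep)) {
    message("removing ", sum(!keep), " group(s): ",
            paste(groups$group[!keep], collapse = ", "))
  }
  groups[keep, , drop = FALSE]
}

#' Prune correlated, missing-heavy, and constant features
#'
#' Before model fitting, features are reduced so that no surviving pair has
#' absolute Pearson correlation above `threshold`. Within a correlated
#' cluster the kept feature is chosen by, in order: (1) stronger marginal
#' correlation with the response odds, (2) not being derived from another
#' feature, (3) being correlated with fewer other features. Features with
#' more than `max_missing` missing values, or no variance, are removed
#' first.
#'
#' @param features Groups x features numeric data frame or matrix.
#' @param odds Response (one value per group).
#' @param threshold Correlation cutoff (default 0.7, strict inequality).
#' @param derived Optional logical per feature: is it derived from a subset
#'   of another feature (disfavoured when breaking clusters)?
#' @param max_missing Maximum tolerated fraction of missing values.
#' @return Character vector of kept feature names.
#' @export
prefilter_features <- function(features, odds, threshold = 0.7,
                               derived = NULL, max_missing = 0.5) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 features")
  if (is.null(derived)) derived <- rep(FALSE, ncol(features))
  names(derived) <- names(features)

  frac_na <- vapply(features, function(f) mean(is.na(f)), numeric(1))
  drop_na <- names(frac_na)[frac_na > max_missing]
  if (length(drop_na)) {
    message("removing feature(s) with >", round(100 * max_missing),
            "% missing values: ", paste(drop_na, collapse = ", "))
  }
  keep <- setdiff(names(features), drop_na)
  const <- keep[vapply(features[keep], function(f) {
    v <- var(f, na.rm = TRUE); !is.finite(v) || v == 0
  }, logical(1))]
  if (length(const)) {
    warning("removing constant feature(s): ", paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  if (length(keep) < 2) return(keep)

  cmat <- abs(cor(features[keep], use = "pairwise.complete.obs"))
  diag(cmat) <- 0
  marg <- vapply(keep, function(f) {
    abs(cor(features[[f]], odds, use = "complete.obs"))
  }, numeric(1))
  repeat {
    high <- which(cmat > threshold, arr.ind = TRUE)
    if (!nrow(high)) break
    # most entangled pair first
    pair_i <- high[which.max(cmat[high]), ]
    a <- keep[pair_i[1]]; b <- keep[pair_i[2]]
    n_hi <- rowSums(cmat > threshold)
    drop <- if (marg[a] != marg[b]) {
      if (marg[a] < marg[b]) a else b
    } else if (derived[a] != derived[b]) {
      if (derived[a]) a else b
    } else if (n_hi[keep == a] != n_hi[keep == b]) {
      if (n_hi[keep == a] > n_hi[keep == b]) a else b
    } else a
    i <- which(keep == drop)
    keep <- keep[-i]; cmat <- cmat[-i, -i, drop = FALSE]; marg <- marg[-i]
    if (length(keep) < 2) break
  }
  keep
}

#' Fit the retention linear model with F-maximizing backward elimination
#'
#' A linear model odds ~ features is fit, the feature with the largest
#' coefficient p-value is dropped, the model refit, and so on down to a
#' single feature; the model returned is the visited model with the largest
#' overall F-statistic (ties broken toward fewer features). With a constant
#' response the intercept-only model is returned and no feature is
#' selected. Feature importance is the decrease in R^2 when the feature is
#' removed from the selected model.
#'
#' @param features Groups x features data frame (candidate set, typically
#'   after [prefilter_features()]).
#' @param odds Response vector (retention odds per group; set
#'   `log_odds = TRUE` to regress on the log scale).
#' @param log_odds Regress log(odds) instead of raw odds.
#' @param weights Optional per-group weights for the fit.
#' @return Object of class `retention_fit`: `selected` features, `model`
#'   (the final `lm`), `coefficients`, `r_squared`, `f_statistic`,
#'   `p_value`, `importance` (named delta-R^2), and the elimination `path`
#'   (data frame of visited models).
#' @export
fit_retention_model <- function(features, odds, log_odds = FALSE,
                                weights = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (length(odds) != n) stop("odds must have one value per group")
  if (n < ncol(features) + 2) {
    stop("need at least ", ncol(features) + 2, " groups for ",
         ncol(features), " features")
  }
  y <- if (log_odds) log(odds) else odds
  dat <- cbind(.y = y, features)

  if (var(y) == 0) {
    fit0 <- lm(.y ~ 1, data = dat, weights = weights)
    return(structure(list(selected = character(0), model = fit0,
                          coefficients = coef(fit0), r_squared = 0,
                          f_statistic = NA_real_, p_value = NA_real_,
                          importance = numeric(0),
                          path = data.frame(step = 0, n_features = 0,
                                            f_statistic = NA_real_,
                                            r_squared = 0),
                          log_odds = log_odds),
                     class = "retention_fit"))
  }

  current <- names(features)
  path <- list()
  best <- NULL
  step <- 0
  while (length(current) >= 1) {
    step <- step + 1
    fml <- stats::reformulate(current, response = ".y")
    fit <- lm(fml, data = dat, weights = weights)
    ali <- is.na(coef(fit))
    if (any(ali)) {
      bad <- names(coef(fit))[ali]
      bad <- intersect(bad, current)
      warning("dropping aliased feature(s): ", paste(bad, collapse = ", "))
      current <- setdiff(current, bad)
      next
    }
    sm <- summary(fit)
    Fst <- unname(sm$fstatistic["value"])
    if (!is.finite(Fst)) Fst <- Inf   # perfect fit: residual variance 0
    path[[step]] <- data.frame(step = step, n_features = length(current),
                               f_statistic = Fst, r_squared = sm$r.squared,
                               features = paste(current, collapse = "+"))
    if (is.null(best) || Fst >= best$F - 1e-12) {
      best <- list(F = Fst, fit = fit, features = current, summary = sm)
    }
    if (length(current) == 1) break
    pv <- coef(sm)[, "Pr(>|t|)"]
    pv <- pv[setdiff(names(pv), "(Intercept)")]
    if (all(!is.finite(pv))) {
      # zero-residual (perfect) fit: p-values are undefined, so rank by
      # coefficient magnitude instead
      cf <- abs(coef(fit)[names(pv)])
      current <- setdiff(current, names(cf)[which.min(cf)])
    } else {
      pv[!is.finite(pv)] <- 1
      current <- setdiff(current, names(pv)[which.max(pv)])
    }
  }
  sm <- best$summary
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat) || !all(is.finite(fstat))) {
    if (is.infinite(best$F)) 0 else NA_real_
  } else unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))

  imp <- vapply(best$features, function(f) {
    rest <- setdiff(best$features, f)
    fml <- if (length(rest)) stats::reformulate(rest, ".y") else .y ~ 1
    sub <- lm(fml, data = dat, weights = weights)
    sm$r.squared - summary(sub)$r.squared
  }, numeric(1))

  structure(list(selected = best$features, model = best$fit,
                 coefficients = coef(best$fit), r_squared = sm$r.squared,
                 f_statistic = best$F, p_value = pval, importance = imp,
                 path = do.call(rbind, path), log_odds = log_odds),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat("Retention linear model (",
      if (x$log_odds) "log-odds" else "odds", " response)\n", sep = "")
  if (!length(x$selected)) {
    cat("  intercept-only model: no informative features\n")
    return(invisible(x))
  }
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat("  R^2:", format(x$r_squared, digits = 4),
      " F:", format(x$f_statistic, digits = 5),
      " p:", format.pval(x$p_value, digits = 4), "\n")
  cat("  importance (delta R^2):",
      paste(names(x$importance), format(x$importance, digits = 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.retention_fit <- function(object, ...) object$coefficients

#' @export
summary.retention_fit <- function(object, ...) summary(object$model, ...)

#' @export
predict.retention_fit <- function(object, newdata = NULL, ...) {
  predict(object$model, newdata = newdata, ...)
}

#' Leave-one-group-out robustness of the retention model
#'
#' Each function group is omitted in turn and the full elimination procedure
#' re-run on the remainder. Reported are the dispersion of each parameter
#' (over refits where the feature was selected) and which omissions change
#' the selected feature set.
#'
#' @inheritParams fit_retention_model
#' @param groups Optional group labels (rownames of `features` by default).
#' @return Object of class `retention_loo`: `parameters` (data frame of
#'   per-parameter mean, sd, relative sd, times selected), `changed`
#'   (labels of omissions whose selected set differs from the full fit),
#'   `fits` (list of refits), `full` (the full-data fit).
#' @export
leave_one_out_robustness <- function(features, odds, log_odds = FALSE,
                                     weights = NULL, groups = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < 5) stop("need at least 5 groups")
  if (is.null(groups)) {
    groups <- rownames(features)
    if (is.null(groups)) groups <- as.character(seq_len(n))
  }
  full <- fit_retention_model(features, odds, log_odds, weights)
  fits <- vector("list", n)
  names(fits) <- groups
  for (i in seq_len(n)) {
    fits[[i]] <- tryCatch(
      fit_retention_model(features[-i, , drop = FALSE], odds[-i],
                          log_odds, weights[-i]),
      error = function(e) e)
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (any(!ok)) {
    warning("refit failed for omission(s): ",
            paste(groups[!ok], collapse = ", "))
  }
  allpar <- unique(c("(Intercept)",
                     unlist(lapply(fits[ok], function(f) names(f$coefficients)))))
  est <- matrix(NA_real_, sum(ok), length(allpar),
                dimnames = list(groups[ok], allpar))
  for (g in groups[ok]) {
    cf <- fits[[g]]$coefficients
    est[g, names(cf)] <- cf
  }
  params <- data.frame(
    parameter = allpar,
    mean = colMeans(est, na.rm = TRUE),
    sd = apply(est, 2, sd, na.rm = TRUE),
    n_selected = colSums(!is.na(est)),
    row.names = NULL
  )
  params$rel_sd <- abs(params$sd / params$mean)
  changed <- groups[ok][!vapply(fits[ok], function(f) {
    setequal(f$selected, full$selected)
  }, logical(1))]
  structure(list(parameters = params, changed = changed, fits = fits,
                 full = full, estimates = est),
            class = "retention_loo")
}

#' @export
print.retention_loo <- function(x, ...) {
  cat("Leave-one-group-out robustness (", nrow(x$estimates),
      " refits)\n", sep = "")
  print(x$parameters, digits = 4)
  if (length(x$changed)) {
    cat("  selection changes when omitting:",
        paste(x$changed, collapse = ", "), "\n")
  } else cat("  selected feature set stable across all omissions\n")
  invisible(x)
}
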