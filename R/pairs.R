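# Comparing extant WGD duplicates to their inferred pre-duplication
# ancestor. Per item (expression condition or cis-regulatory site) a pair is
# in state O (both copies retain the ancestral state), I (exactly one does;
# "partitioned") or II (neither does). Items with an ambiguous ancestral
# call or a missing extant value are dropped item-wise.

#' Classify one pair x item against the ancestral state
#'
#' @param ancestral,stateA,stateB Integer states; any `NA` yields `NA` (the
#'   item is skipped downstream).
#' @return Character vector: `"O"`, `"I"`, `"II"` (vectorized).
#' @export
classify_pair_item <- function(ancestral, stateA, stateB) {
  a <- stateA == ancestral
  b <- stateB == ancestral
  out <- ifelse(a & b, "O", ifelse(xor(a, b), "I", "II"))
  out[is.na(ancestral) | is.na(stateA) | is.na(stateB)] <- NA_character_
  out
}

#' Classify all items of a set of duplicate pairs
#'
#' @param pair Pair identifiers (one per row).
#' @param item Item identifiers.
#' @param ancestral,stateA,stateB States per pair x item.
#' @return Data frame `pair`, `item`, `class`, `retained_by` (`"A"`/`"B"`
#'   for partitioned items, `"both"`/`"neither"` otherwise); `NA`-state rows
#'   are removed.
#' @export
classify_pairs <- function(pair, item, ancestral, stateA, stateB) {
  cls <- classify_pair_item(ancestral, stateA, stateB)
  keep <- !is.na(cls)
  retained <- ifelse(cls == "O", "both",
              ifelse(cls == "II", "neither",
              ifelse(stateA == ancestral, "A", "B")))
  data.frame(pair = pair[keep], item = item[keep], class = cls[keep],
             retained_by = retained[keep], stringsAsFactors = FALSE)
}

#' Per-copy deviation from the ancestral quartile
#'
#' For each pair x item, the deviation of each extant copy from the
#' ancestral quartile (extant - ancestral, in -3..3). Copy 1 is defined as
#' the copy with the higher-or-equal extant quartile, so the grid of
#' (deviation 1, deviation 2) is upper-triangular by construction.
#'
#' @inheritParams classify_pairs
#' @return Data frame `pair`, `item`, `dev1`, `dev2` with `dev1 >= dev2`.
#' @export
deviation_records <- function(pair, item, ancestral, stateA, stateB) {
  keep <- !(is.na(ancestral) | is.na(stateA) | is.na(stateB))
  pair <- pair[keep]; item <- item[keep]
  ancestral <- ancestral[keep]; stateA <- stateA[keep]; stateB <- stateB[keep]
  hi <- pmax(stateA, stateB); lo <- pmin(stateA, stateB)
  data.frame(pair = pair, item = item,
             dev1 = hi - ancestral, dev2 = lo - ancestral,
             stringsAsFactors = FALSE)
}

#' Permutation z-scores for a paired-value grid
#'
#' Observed counts of each (x, y) cell are compared with counts expected
#' when the pairing is broken: in each replicate the y values are re-drawn
#' as a random re-pairing against the x pool (a permutation of the pooled y
#' values). z = (observed - null mean) / null sd; cells with null sd 0 get
#' `NA` z.
#'
#' @param x,y Paired discrete values (e.g. extant and ancestral quartiles,
#'   or the two deviations of a pair). `NA` pairs are dropped.
#' @param n_perm Number of permutation replicates (>= 100).
#' @param levels_x,levels_y Cell levels; defaults to the observed ranges.
#' @return Object of class `zscore_grid`: matrices `observed`, `mean`,
#'   `sd`, `z` (rows = x levels, columns = y levels).
#' @export
permutation_zscores <- function(x, y, n_perm = 1000,
                                levels_x = NULL, levels_y = NULL) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (!length(x)) stop("empty pool after dropping missing values")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (is.null(levels_x)) levels_x <- sort(unique(x))
  if (is.null(levels_y)) levels_y <- sort(unique(y))
  fx <- factor(x, levels = levels_x)
  fy <- factor(y, levels = levels_y)
  observed <- table(fx, fy)
  counts <- array(0L, c(n_perm, length(levels_x), length(levels_y)))
  for (r in seq_len(n_perm)) {
    counts[r, , ] <- table(fx, fy[sample.int(length(y))])
  }
  mu <- apply(counts, c(2, 3), mean)
  sdev <- apply(counts, c(2, 3), sd)
  z <- (unclass(observed) - mu) / sdev
  z[sdev == 0] <- NA_real_
  dimnames(mu) <- dimnames(sdev) <- dimnames(z) <- dimnames(observed)
  structure(list(observed = unclass(observed), mean = mu, sd = sdev, z = z,
                 n_perm = n_perm, n = length(x)),
            class = "zscore_grid")
}

#' @export
print.zscore_grid <- function(x, ...) {
  cat("Permutation z-score grid (", x$n, " pairs, ", x$n_perm,
      " permutations)\n", sep = "")
  print(round(x$z, 2))
  invisible(x)
}

#' Observed vs expected pair-state fractions
#'
#' Summarizes how often duplicate pairs are in state O / I / II across
#' items, against an expectation from randomly re-pairing duplicates: each
#' gene keeps its own per-item ancestral-retention profile, but copy B
#' profiles are shuffled across pairs (within strata when given). For a
#' permuted pairing, items present in both members' profiles are classified
#' as usual.
#'
#' @param retention Data frame with columns `pair`, `item`, `retA`, `retB`
#'   (logical: does that copy retain the ancestral state for the item) and
#'   optionally `stratum` (e.g. WGD event x data subset) within which
#'   re-pairing is confined.
#' @param n_rep Number of re-pairing replicates.
#' @return Object of class `pair_summary`: `observed` and `expected`
#'   fractions of O/I/II, permutation `sd` and `z`.
#' @export
pair_expression_summary <- function(retention, n_rep = 1000) {
  need <- c("pair", "item", "retA", "retB")
  if (!all(need %in% names(retention))) {
    stop("retention needs columns: ", paste(need, collapse = ", "))
  }
  if (length(unique(retention$pair)) < 2) stop("need at least 2 pairs")
  if (is.null(retention$stratum)) retention$stratum <- "all"
  frac3 <- function(retA, retB) {
    cls <- ifelse(retA & retB, "O", ifelse(xor(retA, retB), "I", "II"))
    tab <- table(factor(cls, levels = c("O", "I", "II")))
    as.vector(tab) / sum(tab)
  }
  obs <- frac3(retention$retA, retention$retB)
  perm <- matrix(0, n_rep, 3)
  strata <- split(retention, retention$stratum)
  # wide per-stratum profile matrices (pairs x items, NA where a pair lacks
  # the item) let a re-pairing replicate be a row permutation of B
  wide <- lapply(strata, function(d) {
    pairs <- unique(d$pair); items <- unique(d$item)
    A <- B <- matrix(NA, length(pairs), length(items),
                     dimnames = list(pairs, items))
    ij <- cbind(match(d$pair, pairs), match(d$item, items))
    A[ij] <- d$retA; B[ij] <- d$retB
    list(A = A, B = B)
  })
  for (r in seq_len(n_rep)) {
    num <- c(0, 0, 0)
    for (wd in wide) {
      Bp <- wd$B[sample.int(nrow(wd$B)), , drop = FALSE]
      both <- !is.na(wd$A) & !is.na(Bp)
      a <- wd$A[both]; b <- Bp[both]
      num <- num + c(sum(a & b), sum(xor(a, b)), sum(!a & !b))
    }
    perm[r, ] <- num / sum(num)
  }
  mu <- colMeans(perm)
  sdev <- apply(perm, 2, sd)
  z <- (obs - mu) / sdev
  z[sdev == 0] <- NA_real_
  names(obs) <- names(mu) <- names(sdev) <- names(z) <- c("O", "I", "II")
  structure(list(observed = obs, expected = mu, sd = sdev, z = z,
                 n_items = nrow(retention), n_rep = n_rep),
            class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  m <- rbind(observed = x$observed, expected = x$expected, z = x$z)
  cat("Pair-state fractions over", x$n_items, "items (",
      x$n_rep, "re-pairings )\n")
  print(round(m, 3))
  invisible(x)
}

#' Count novel and retained-ancestral cis-regulatory sites per pair
#'
#' A novel site is present in an extant copy but absent from the inferred
#' ancestor; a retained site is present in both. Sites with an ambiguous
#' ancestral call are skipped.
#'
#' @param anc_sites Pairs x sites matrix of ancestral presence calls (0/1,
#'   `NA` = ambiguous).
#' @param sitesA,sitesB Pairs x sites 0/1 matrices for the two extant copies.
#' @param ancestral_copy Character vector per pair: which copy (`"A"`/`"B"`)
#'   is the designated ancestral copy (from the asymmetry analysis).
#' @return Data frame per pair: `novel_ancestral`, `novel_nonancestral`,
#'   `retained_ancestral_copy`, `retained_nonancestral_copy`.
#' @export
novel_site_counts <- function(anc_sites, sitesA, sitesB, ancestral_copy) {
  anc_sites <- as.matrix(anc_sites)
  sitesA <- as.matrix(sitesA); sitesB <- as.matrix(sitesB)
  stopifnot(nrow(anc_sites) == nrow(sitesA), nrow(sitesA) == nrow(sitesB),
            length(ancestral_copy) == nrow(anc_sites))
  cnt <- function(extant, anc, what) {
    m <- !is.na(anc) & !is.na(extant)
    if (what == "novel") rowSums(m & extant == 1 & anc == 0)
    else rowSums(m & extant == 1 & anc == 1)
  }
  novA <- cnt(sitesA, anc_sites, "novel"); novB <- cnt(sitesB, anc_sites, "novel")
  retA <- cnt(sitesA, anc_sites, "ret");   retB <- cnt(sitesB, anc_sites, "ret")
  isA <- ancestral_copy == "A"
  data.frame(
    novel_ancestral = ifelse(isA, novA, novB),
    novel_nonancestral = ifelse(isA, novB, novA),
    retained_ancestral_copy = ifelse(isA, retA, retB),
    retained_nonancestral_copy = ifelse(isA, retB, retA)
  )
}

#' Excess of novel cis-regulatory sites in the non-ancestral copy
#'
#' Tests whether novel sites accumulate preferentially in the copy that
#' inherited fewer ancestral states. Two views: (1) a sign test — among
#' pairs with at least one novel site, is the non-ancestral copy the one
#' with more novel sites more than half the time (exact binomial)? (2) a
#' pooled 2x2 enrichment — copy type x site status (novel vs retained
#' ancestral), reporting the exact conditional (noncentral hypergeometric
#' MLE) odds ratio with Fisher's exact p-value.
#'
#' @param counts Data frame from [novel_site_counts()] (or with the same
#'   columns).
#' @param alternative Direction of the sign test; the default `"greater"`
#'   tests for excess in the non-ancestral copy.
#' @return Object of class `novel_site_test`: per-pair `difference`
#'   (novel non-ancestral minus novel ancestral), sign-test counts and
#'   p-value, fractions of pairs with novel sites only in one copy, and the
#'   pooled Fisher odds ratio/p.
#' @export
novel_site_analysis <- function(counts, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  diff <- counts$novel_nonancestral - counts$novel_ancestral
  any_novel <- (counts$novel_nonancestral + counts$novel_ancestral) >= 1
  n_tested <- sum(any_novel)
  successes <- sum(diff > 0 & any_novel)
  sign_test <- if (n_tested > 0) {
    binom.test(successes, n_tested, p = 0.5, alternative = alternative)
  } else NULL
  only_non <- sum(any_novel & counts$novel_ancestral == 0) / max(n_tested, 1)
  only_anc <- sum(any_novel & counts$novel_nonancestral == 0) / max(n_tested, 1)
  tab <- matrix(c(sum(counts$novel_nonancestral), sum(counts$retained_nonancestral_copy),
                  sum(counts$novel_ancestral), sum(counts$retained_ancestral_copy)),
                2, 2, byrow = TRUE,
                dimnames = list(copy = c("non-ancestral", "ancestral"),
                                site = c("novel", "retained")))
  fish <- if (all(rowSums(tab) > 0)) fisher.test(tab) else NULL
  or_hat <- if (is.null(fish)) NA_real_ else
    cond_mle_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  structure(list(
    difference = diff, n_pairs_with_novel = n_tested,
    n_nonancestral_excess = successes,
    p_sign = if (is.null(sign_test)) NA_real_ else sign_test$p.value,
    sign_test = sign_test,
    frac_only_nonancestral = only_non, frac_only_ancestral = only_anc,
    table = tab,
    odds_ratio = or_hat,
    p_enrichment = if (is.null(fish)) NA_real_ else fish$p.value,
    fisher = fish
  ), class = "novel_site_test")
}

#' @export
print.novel_site_test <- function(x, ...) {
  cat("Novel-site excess in non-ancestral copies\n")
  cat("  ", x$n_nonancestral_excess, "of", x$n_pairs_with_novel,
      "pairs with novel sites favour the non-ancestral copy; sign-test p:",
      format.pval(x$p_sign, digits = 4), "\n")
  cat("  pooled enrichment odds ratio:", format(x$odds_ratio, digits = 4),
      " Fisher p:", format.pval(x$p_enrichment, digits = 4), "\n")
  invisible(x)
}
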