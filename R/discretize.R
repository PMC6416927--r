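#' Discretize expression values into quartile states
#'
#' Continuous expression values (log2 scale) are mapped to four states
#' 0--3 by the empirical quartiles of each experiment, so that states are
#' comparable across platforms and conditions. Bins are lower-closed /
#' upper-open on the quartile boundaries, except the top bin which is closed;
#' ties on a boundary collapse downward. The rule is deterministic and does
#' not depend on row order.
#'
#' @param mat Numeric matrix or data frame, genes x conditions. `NA` marks
#'   missing values and stays `NA` in the output.
#' @param experiments Character or factor of length `ncol(mat)` assigning each
#'   condition (column) to an experiment; quartiles are computed within an
#'   experiment over all of its cells. Default: one experiment per column.
#' @return Integer matrix of the same shape with values in `0:3` or `NA`.
#' @export
discretize_expression <- function(mat, experiments = colnames(mat)) {
  mat <- as.matrix(mat)
  if (is.null(experiments)) experiments <- as.character(seq_len(ncol(mat)))
  if (length(experiments) != ncol(mat)) {
    stop("experiments must have one entry per column")
  }
  out <- matrix(NA_integer_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (ex in unique(experiments)) {
    cols <- which(experiments == ex)
    vals <- mat[, cols]
    ok <- !is.na(vals)
    if (sum(ok) < 4) {
      warning("experiment '", ex, "' has fewer than 4 values; all set to NA")
      next
    }
    qs <- quantile(vals[ok], probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    states <- findInterval(vals, qs, left.open = TRUE)  # boundary value -> lower bin
    states[!ok] <- NA_integer_
    out[, cols] <- as.integer(states)
  }
  out
}

#' Differential-expression subset (stress minus control)
#'
#' Builds the "Diff" data subset: the element-wise log2 difference between
#' each stress condition and its matched control. The stress/control pairing
#' is supplied explicitly since it is experiment metadata, not recoverable
#' from column names.
#'
#' @param stress Numeric matrix, genes x stress conditions (log2 scale).
#' @param control Numeric matrix, genes x control conditions (log2 scale),
#'   same genes in the same order.
#' @param pairing Data frame with columns `stress` and `control` naming the
#'   matched columns. Every stress column used must appear exactly once.
#' @return Matrix genes x stress-conditions of differences; `NA` where either
#'   member is missing.
#' @export
compute_diff_subset <- function(stress, control, pairing) {
  stress <- as.matrix(stress); control <- as.matrix(control)
  if (nrow(stress) != nrow(control)) stop("gene dimensions differ")
  if (!all(c("stress", "control") %in% names(pairing))) {
    stop("pairing needs 'stress' and 'control' columns")
  }
  bad_s <- setdiff(pairing$stress, colnames(stress))
  bad_c <- setdiff(pairing$control, colnames(control))
  if (length(bad_s) || length(bad_c)) {
    stop("unmatched conditions: ", paste(c(bad_s, bad_c), collapse = ", "))
  }
  out <- stress[, pairing$stress, drop = FALSE] -
    control[, pairing$control, drop = FALSE]
  colnames(out) <- pairing$stress
  rownames(out) <- rownames(stress)
  out
}
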