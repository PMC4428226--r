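#' Threshold classification of observed patterns as spurious
#'
#' Given a per-pattern test statistic (the estimated frequency, or the
#' naive proportion `y/N`) over the patterns observed in the reads, and the
#' known true distribution (so: simulated data), declare a pattern spurious
#' when its statistic is less than or equal to the threshold `K` (ties are
#' declared spurious).  A declaration is a true positive when the pattern
#' really is absent (`theta = 0`), a false positive when it is present; a
#' pattern above threshold is a true negative when present and a false
#' negative when absent.  This is a classifier for benchmarking, not a
#' hypothesis test: the threshold has no p-value interpretation.
#'
#' @param stat Named numeric vector: the statistic for every pattern with
#'   `y > 0` (its names define the set of patterns considered).
#' @param true_theta Named true distribution; patterns absent from it count
#'   as frequency zero.
#' @param K Threshold in `[0, 1]`.
#' @return An object of class `"pattern_classification"`: list with `K`,
#'   `TP`, `FP`, `TN`, `FN`, `TPR` (`TP/(TP+FN)`), `FPR` (`FP/(FP+TN)`);
#'   rates are `NA` when their denominator is zero.
#' @examples
#' fx <- table1_fixture()
#' fit <- estimate_patterns(fx$counts, model = fx$model)
#' classify_at_threshold(coef(fit)[names(naive_estimate(fx$counts))],
#'                       fx$theta, K = 0)
#' @seealso [tpr_fpr_curve()]
#' @export
classify_at_threshold <- function(stat, true_theta, K) {
  if (length(K) != 1L || is.na(K) || K < 0 || K > 1)
    stop("'K' must be a single probability in [0, 1]")
  if (is.null(names(stat))) stop("'stat' must be named by pattern")
  truth <- stats::setNames(numeric(length(stat)), names(stat))
  hit <- intersect(names(stat), names(true_theta))
  truth[hit] <- true_theta[hit]
  called <- stat <= K
  TP <- sum(called & truth == 0)
  FP <- sum(called & truth > 0)
  TN <- sum(!called & truth > 0)
  FN <- sum(!called & truth == 0)
  structure(list(K = K, TP = TP, FP = FP, TN = TN, FN = FN,
                 TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
                 FPR = if (FP + TN > 0) FP / (FP + TN) else NA_real_),
            class = "pattern_classification")
}

#' @export
print.pattern_classification <- function(x, ...) {
  cat(sprintf("K = %g: TP %d, FP %d, TN %d, FN %d; TPR %s, FPR %s\n",
              x$K, x$TP, x$FP, x$TN, x$FN,
              format(x$TPR, digits = 4), format(x$FPR, digits = 4)))
  invisible(x)
}

#' TPR/FPR curve over a threshold grid
#'
#' Sweeps [classify_at_threshold()] over a grid of thresholds.  The default
#' grid is closed — `0`, `1` and every distinct value of the statistic — so
#' every step of the (necessarily non-decreasing) TPR and FPR step
#' functions is represented exactly.
#'
#' @inheritParams classify_at_threshold
#' @param K_grid Monotone increasing thresholds; default as described.
#' @return A data frame with columns `K`, `TP`, `FP`, `TN`, `FN`, `TPR`,
#'   `FPR`, one row per threshold.
#' @export
tpr_fpr_curve <- function(stat, true_theta, K_grid = NULL) {
  if (is.null(K_grid))
    K_grid <- sort(unique(c(0, 1, as.numeric(stat))))
  if (!length(K_grid)) stop("'K_grid' is empty")
  if (is.unsorted(K_grid, strictly = FALSE))
    stop("'K_grid' must be monotone increasing")
  rows <- lapply(K_grid, function(K) {
    cl <- classify_at_threshold(stat, true_theta, K)
    data.frame(K = K, TP = cl$TP, FP = cl$FP, TN = cl$TN, FN = cl$FN,
               TPR = cl$TPR, FPR = cl$FPR)
  })
  do.call(rbind, rows)
}
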