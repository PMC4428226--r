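#' @export
print.pattern_fit <- function(x, ...) {
  obs <- names(x$naive)
  cat(sprintf("Methylation pattern frequency fit (%s mode)\n", x$mode))
  cat(sprintf("  locus: %d CpG sites; %d observed patterns; N_read = %d\n",
              x$counts$n, length(obs), x$counts$N))
  cat(sprintf("  error model: epsilon = %s, eta = %s\n",
              format(x$model$epsilon),
              paste(format(x$model$eta), collapse = ", ")))
  cat(sprintf("  log-likelihood: %.4f (%d EM sweeps%s)\n", x$logLik,
              x$iterations, if (x$converged) "" else "; NOT converged"))
  cat(sprintf("  patterns called spurious: %d of %d observed\n",
              length(x$spurious), length(obs)))
  invisible(x)
}

#' Summarise a pattern frequency fit
#'
#' @param object A `pattern_fit`.
#' @param all_patterns Include rows for patterns with zero reads (slow mode
#'   searches them); default `FALSE`, matching the convention that count
#'   tables list only observed patterns.
#' @param ... Unused.
#' @return A `summary.pattern_fit`: the fit plus a `table` data frame with
#'   columns `pattern`, `y`, `y_over_N`, `theta_hat`, `spurious`.
#' @export
summary.pattern_fit <- function(object, all_patterns = FALSE, ...) {
  pats <- if (all_patterns) names(object$theta) else names(object$naive)
  y <- stats::setNames(integer(length(pats)), pats)
  y[names(object$naive)] <- object$counts$counts[
    match(names(object$naive), object$counts$patterns)]
  theta <- stats::setNames(numeric(length(pats)), pats)
  present <- intersect(pats, names(object$theta))
  theta[present] <- object$theta[present]
  tab <- data.frame(pattern = pats, y = as.integer(y),
                    y_over_N = as.numeric(y) / object$counts$N,
                    theta_hat = as.numeric(theta),
                    spurious = y > 0 & theta == 0,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$pattern, method = "radix"), ]
  rownames(tab) <- NULL
  structure(list(fit = object, table = tab), class = "summary.pattern_fit")
}

#' @export
print.summary.pattern_fit <- function(x, digits = 4L, ...) {
  print(x$fit)
  tab <- x$table
  tab$y_over_N <- signif(tab$y_over_N, digits)
  tab$theta_hat <- signif(tab$theta_hat, digits)
  cat("\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pattern_fit <- function(object, ...) object$theta

#' @export
logLik.pattern_fit <- function(object, ...) {
  structure(object$logLik,
            df = sum(object$theta > 0) - 1L,
            nobs = object$counts$N, class = "logLik")
}

#' @export
fitted.pattern_fit <- function(object, ...) {
  y <- observed_counts(object$counts)
  support <- names(object$theta)[object$theta > 0]
  M <- transition_submatrix(support, names(y), object$model)
  drop(crossprod(M, object$theta[support]))
}

#' Predictions from a pattern frequency fit
#'
#' @param object A `pattern_fit`.
#' @param type `"theta"`: the estimated pattern distribution; `"phi"`: the
#'   implied registered-read distribution over all `2^n` patterns;
#'   `"marginal"`: per-site marginal methylation levels.
#' @param ... Unused.
#' @export
predict.pattern_fit <- function(object,
                                type = c("theta", "phi", "marginal"), ...) {
  type <- match.arg(type)
  switch(type,
         theta = object$theta,
         phi = read_distribution(object$theta / sum(object$theta),
                                 object$model),
         marginal = marginal_methylation(object))
}

#' @export
residuals.pattern_fit <- function(object, ...) {
  y <- observed_counts(object$counts)
  phi <- fitted(object)
  N <- object$counts$N
  (y - N * phi) / sqrt(N * phi * (1 - phi))
}

#' Plot observed proportions and estimated pattern frequencies
#'
#' Observed patterns in lexicographic order on the x axis; naive read
#' proportions `y/N` and the estimated distribution as paired points, with
#' spurious calls marked at zero.  An optional true distribution (for
#' simulated data) is overlaid.
#'
#' @param x A `pattern_fit`.
#' @param truth Optional named true distribution to overlay.
#' @param log Use a log y axis (zeros are dropped from the log plot).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pattern_fit <- function(x, truth = NULL, log = FALSE, ...) {
  pats <- names(x$naive)
  idx <- seq_along(pats)
  est <- x$theta[pats]
  ylim <- range(c(x$naive, est, if (!is.null(truth)) truth[pats]),
                na.rm = TRUE)
  graphics::plot(idx, x$naive, pch = 3, col = "blue", xaxt = "n",
                 xlab = "methylation pattern (lexicographic)",
                 ylab = "frequency", ylim = ylim,
                 log = if (log) "y" else "", ...)
  graphics::axis(1, at = idx, labels = pats, las = 2,
                 cex.axis = min(1, 12 / max(nchar(pats), 6)))
  graphics::points(idx, est, pch = 4, col = "red")
  if (!is.null(truth)) {
    tr <- stats::setNames(numeric(length(pats)), pats)
    tr[intersect(pats, names(truth))] <-
      truth[intersect(pats, names(truth))]
    graphics::points(idx, tr, pch = 16, col = "black", cex = 0.6)
  }
  graphics::legend("topright", bty = "n", pch = c(3, 4, if (!is.null(truth)) 16),
                   col = c("blue", "red", if (!is.null(truth)) "black"),
                   legend = c("y/N", "estimate", if (!is.null(truth)) "truth"))
  invisible(x)
}

#' Simulate new count tables from a fitted distribution
#'
#' Draws reads from the estimated distribution pushed through the fitted
#' error model, mirroring the generative model of the fit.
#'
#' @param object A `pattern_fit`.
#' @param nsim Number of simulated count tables.
#' @param seed Optional seed, handled as in [stats::simulate()].
#' @param n_reads Reads per simulation (default: as in the fitted data).
#' @param ... Passed to [simulate_reads()].
#' @return A list of `nsim` [pattern_counts()] objects with a `"seed"`
#'   attribute.
#' @export
simulate.pattern_fit <- function(object, nsim = 1, seed = NULL,
                                 n_reads = NULL, ...) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  rng_state <- get(".Random.seed", envir = globalenv())
  if (!is.null(seed)) {
    set.seed(seed)
    on.exit(assign(".Random.seed", rng_state, envir = globalenv()))
  }
  if (is.null(n_reads)) n_reads <- object$counts$N
  theta <- object$theta[object$theta > 0]
  theta <- theta / sum(theta)
  out <- lapply(seq_len(nsim), function(i)
    simulate_reads(theta, n_reads, object$model, ...)$counts)
  attr(out, "seed") <- if (is.null(seed)) rng_state else seed
  out
}
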