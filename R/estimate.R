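#' Estimate the methylation pattern distribution at a locus
#'
#' Fits the constrained maximum-likelihood estimate of the true methylation
#' pattern (epiallele) distribution `theta` from observed pattern read
#' counts, correcting for incomplete bisulphite conversion (`epsilon`) and
#' per-site sequencing error (`eta`).  The observed counts are modelled as a
#' multinomial sample from `phi = theta %*% M`, where `M` is the
#' Kronecker-product misclassification matrix of [error_model()]; the
#' log-likelihood `sum(y * log(phi))` is maximised over the probability
#' simplex.
#'
#' Two search modes are available.  The default `"fast"` mode restricts the
#' support of `theta` to the patterns actually observed (`y > 0`), which is
#' accurate in practice because patterns with zero reads essentially never
#' carry estimated mass, and scales to large `n` as long as the number of
#' observed patterns stays moderate (a warning is issued above 200).  The
#' `"slow"` mode searches all `2^n` patterns and is refused for `n > 8`
#' unless `force = TRUE`.
#'
#' The optimiser is an expectation-maximisation iteration with multiplicative
#' updates `theta_j <- theta_j * sum_k(y_k * M[j,k] / phi_k) / N`, which
#' preserves the simplex and drives inactive components to the boundary; the
#' constrained MLE is unique, so the result does not depend on the (strictly
#' interior) start.  After convergence a boundary-refinement step
#' ([boundary_refine()]) compares the likelihood against nearby boundary
#' points, snapping near-zero components to exactly zero whenever the
#' re-optimised boundary likelihood is no worse (ties prefer the more
#' parsimonious boundary point).  Observed patterns whose final estimate is
#' identically zero are called spurious.
#'
#' @param counts A [pattern_counts()] object (or something coercible via
#'   `pattern_counts()` when given as a data frame with columns `pattern`
#'   and `count`).
#' @param epsilon,eta Error rates, passed to [error_model()]; ignored when
#'   `model` is supplied.  `eta` may be a scalar (uniform across sites) or a
#'   length-`n` vector.
#' @param mode `"fast"` (default) or `"slow"`; see Details.
#' @param model An [error_model()], overriding `epsilon`/`eta`.
#' @param tol Convergence tolerance: stop when the log-likelihood improves
#'   by less than `tol` nats between sweeps (default 1e-10).
#' @param max_iter Maximum EM sweeps per optimisation stage (default 1e5).
#' @param zero_tol Components below this value after convergence are
#'   candidates for boundary snapping (default 1e-5).  Snapping itself is
#'   decided by likelihood comparison, not by this magnitude threshold.
#' @param force Override the `n > 8` slow-mode guard.
#' @return An object of class `"pattern_fit"`, a list with components
#'   \describe{
#'     \item{theta}{named estimated distribution over the searched support
#'       (exact zeros for snapped components).}
#'     \item{spurious}{observed patterns with `y > 0` and estimate exactly 0.}
#'     \item{logLik}{maximised log-likelihood (nats).}
#'     \item{mode, counts, model}{the inputs.}
#'     \item{naive}{the naive proportions `y / N` over observed patterns.}
#'     \item{iterations, converged, boundary_snaps}{diagnostics.}
#'   }
#'   Methods: `print`, `summary`, `coef`, `logLik`, `fitted`, `predict`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' fx <- table1_fixture()
#' fit <- estimate_patterns(fx$counts, model = fx$model)
#' fit
#' coef(fit)[c("000000", "111111")]
#' spurious_patterns(fit)
#' marginal_methylation(fit)
#' @seealso [boundary_refine()], [spurious_patterns()], [pattern_loglik()],
#'   [simulate_reads()]
#' @export
estimate_patterns <- function(counts, epsilon = 0, eta = 0,
                              mode = c("fast", "slow"), model = NULL,
                              tol = 1e-10, max_iter = 1e5L,
                              zero_tol = 1e-5, force = FALSE) {
  counts <- as_pattern_counts(counts)
  mode <- match.arg(mode)
  if (is.null(model)) model <- error_model(epsilon, eta)
  stopifnot(inherits(model, "error_model"))
  eta_vector(model, counts$n)  # dimension check up front

  y <- observed_counts(counts)
  observed <- names(y)
  if (mode == "slow") {
    if (counts$n > 8L && !force)
      stop("slow mode searches all 2^n patterns and is impractical for n > 8 ",
           "(n = ", counts$n, "); use mode = \"fast\" or force = TRUE")
    support <- all_patterns(counts$n)
  } else {
    if (length(observed) > 200L)
      warning("fast mode with ", length(observed), " observed patterns; ",
              "expect long run times above ~200")
    support <- observed
  }

  M <- transition_submatrix(support, observed, model)
  ysup <- stats::setNames(numeric(length(support)), support)
  ysup[observed] <- y
  theta0 <- (ysup + 0.5) / (counts$N + length(support) / 2)

  fit <- em_maximise(theta0, M, y, tol = tol, max_iter = max_iter)
  ref <- refine_to_boundary(fit$theta, M, y, fit$logLik,
                            zero_tol = zero_tol, tol = tol,
                            max_iter = max_iter)

  theta <- stats::setNames(ref$theta, support)
  structure(
    list(theta = theta,
         spurious = observed[theta[observed] == 0],
         logLik = ref$logLik,
         mode = mode, counts = counts, model = model,
         naive = y / counts$N,
         iterations = fit$iterations + ref$iterations,
         converged = fit$converged && ref$converged,
         boundary_snaps = ref$snapped,
         tol = tol, zero_tol = zero_tol,
         call = match.call()),
    class = "pattern_fit")
}

as_pattern_counts <- function(counts) {
  if (inherits(counts, "pattern_counts")) return(counts)
  if (is.data.frame(counts) && all(c("pattern", "count") %in% names(counts)))
    return(pattern_counts(counts$pattern, counts$count))
  stop("'counts' must be a pattern_counts object or a data frame with ",
       "columns 'pattern' and 'count'")
}

# EM for the multinomial misclassification likelihood.  theta0 strictly
# interior on its support; exact zeros in theta0 are preserved, so the same
# routine optimises over reduced supports during boundary refinement.
em_maximise <- function(theta0, M, y, tol, max_iter) {
  N <- sum(y)
  theta <- theta0 / sum(theta0)
  ll_old <- -Inf
  ll <- em_loglik(theta, M, y)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    phi <- drop(crossprod(M, theta))
    theta <- theta * drop(M %*% (y / phi)) / N
    ll_old <- ll
    ll <- em_loglik(theta, M, y)
    if (ll - ll_old < tol) break
  }
  list(theta = theta, logLik = ll, iterations = iter,
       converged = iter < max_iter)
}

em_loglik <- function(theta, M, y) {
  phi <- drop(crossprod(M, theta))
  if (any(phi == 0)) return(-Inf)
  sum(y * log(phi))
}

# Likelihood-driven snap of near-zero components to the simplex boundary.
# Tries zeroing all candidates jointly first, then singly; each trial
# renormalises and re-optimises over the reduced support, and is adopted
# when its likelihood is no worse than the current one (within tie_tol, so
# exact ties go to the more parsimonious boundary point).
refine_to_boundary <- function(theta, M, y, ll, zero_tol, tol, max_iter,
                               tie_tol = 1e-9) {
  snapped <- character(0)
  iters <- 0L
  converged <- TRUE
  trial <- function(idx) {
    th <- theta
    th[idx] <- 0
    if (sum(th) <= 0) return(NULL)
    em_maximise(th / sum(th), M, y, tol, max_iter)
  }
  repeat {
    cand <- which(theta > 0 & theta < zero_tol)
    if (!length(cand)) break
    adopted <- FALSE
    joint <- trial(cand)
    if (!is.null(joint) && joint$logLik >= ll - tie_tol) {
      theta <- joint$theta
      theta[cand] <- 0
      ll <- joint$logLik
      iters <- iters + joint$iterations
      converged <- converged && joint$converged
      snapped <- c(snapped, names(theta)[cand])
      next
    }
    if (!is.null(joint)) iters <- iters + joint$iterations
    if (length(cand) > 1L) {
      singles <- lapply(cand, trial)
      lls <- vapply(singles, function(f) if (is.null(f)) -Inf else f$logLik,
                    numeric(1L))
      iters <- iters + sum(vapply(singles, function(f)
        if (is.null(f)) 0L else f$iterations, integer(1L)))
      ok <- which(lls >= ll - tie_tol)
      if (length(ok)) {
        best <- ok[which.max(lls[ok])]
        theta <- singles[[best]]$theta
        theta[cand[best]] <- 0
        ll <- lls[best]
        converged <- converged && singles[[best]]$converged
        snapped <- c(snapped, names(theta)[cand[best]])
        adopted <- TRUE
      }
    }
    if (!adopted) break
  }
  list(theta = theta, logLik = ll, snapped = snapped,
       iterations = iters, converged = converged)
}

#' Snap near-zero components of a distribution to the simplex boundary
#'
#' Post-optimisation refinement step of [estimate_patterns()], exposed for
#' direct use.  Every component of `theta` below `zero_tol` is a candidate;
#' the log-likelihood is evaluated with the candidates set to exactly zero
#' (jointly and singly), the remaining mass renormalised and re-optimised
#' over the reduced support, and the best such boundary point is adopted
#' whenever its likelihood is greater than or equal to the current one
#' (within 1e-9 nats, so ties prefer the boundary).  Components of the
#' returned distribution are exactly zero or strictly positive.
#'
#' @param theta Named pattern distribution (a converged interior estimate).
#' @param counts A [pattern_counts()] object.
#' @param model An [error_model()].
#' @inheritParams estimate_patterns
#' @return The refined named distribution.
#' @export
boundary_refine <- function(theta, counts, model, zero_tol = 1e-5,
                            tol = 1e-10, max_iter = 1e5L) {
  counts <- as_pattern_counts(counts)
  validate_distribution(theta)
  y <- observed_counts(counts)
  M <- transition_submatrix(names(theta), names(y), model)
  ll <- em_loglik(theta, M, y)
  ref <- refine_to_boundary(theta, M, y, ll, zero_tol = zero_tol,
                            tol = tol, max_iter = max_iter)
  stats::setNames(ref$theta, names(theta))
}

#' Multinomial misclassification log-likelihood
#'
#' `sum_k y_k * log(phi_k)` over observed patterns, with
#' `phi = theta %*% M`; `-Inf` when some observed pattern has zero
#' probability under `theta` pushed through the error model.
#'
#' @inheritParams boundary_refine
#' @return Log-likelihood in nats.
#' @export
pattern_loglik <- function(theta, counts, model) {
  counts <- as_pattern_counts(counts)
  validate_distribution(theta)
  if (nchar(names(theta)[1L]) != counts$n)
    stop("'theta' patterns and 'counts' patterns have different lengths")
  y <- observed_counts(counts)
  support <- names(theta)[theta > 0]
  if (!length(support)) return(-Inf)
  M <- transition_submatrix(support, names(y), model)
  em_loglik(theta[support], M, y)
}

#' Observed patterns called spurious by a fit
#'
#' Patterns with a positive read count whose estimated frequency is
#' identically zero: the fit attributes every one of their reads to
#' non-conversion or sequencing error acting on other patterns.
#'
#' @param fit A [estimate_patterns()] fit.
#' @return Character vector of pattern strings.
#' @export
spurious_patterns <- function(fit) {
  stopifnot(inherits(fit, "pattern_fit"))
  fit$spurious
}

#' Per-site marginal methylation levels
#'
#' Collapses a pattern distribution to the pointwise methylation level of
#' each CpG site: site `s` gets the total probability of all patterns
#' methylated at `s`.
#'
#' @param theta A named pattern distribution, or a `pattern_fit` (its
#'   estimated distribution is used).
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
marginal_methylation <- function(theta) {
  if (inherits(theta, "pattern_fit")) theta <- theta$theta
  validate_distribution(theta)
  bits <- pattern_bit_matrix(names(theta))
  drop(theta %*% bits)
}

#' Naive pattern frequency estimate
#'
#' The raw read proportions `y / N_read` over observed patterns, ignoring
#' the error model.  Useful as the comparison statistic for
#' [classify_at_threshold()]; it is never zero for an observed pattern, so
#' it cannot call any pattern spurious.
#'
#' @param counts A [pattern_counts()] object.
#' @return Named numeric vector over patterns with `y > 0`.
#' @export
naive_estimate <- function(counts) {
  counts <- as_pattern_counts(counts)
  observed_counts(counts) / counts$N
}

#' Matrix-inversion pattern frequency estimate
#'
#' The textbook-looking estimator `theta = (y / N) %*% solve(M)`: invert the
#' misclassification matrix applied to the naive multinomial MLE.  Exposed
#' for comparison only — the error matrix shrinks the simplex, so for any
#' realistic data (where many counts are zero) the inverted estimate falls
#' outside the simplex, with negative components.  Use
#' [estimate_patterns()] for inference.
#'
#' @param counts A [pattern_counts()] object.
#' @param model An [error_model()].
#' @param dense_limit Passed to [full_transition_matrix()].
#' @return Named numeric vector over all `2^n` patterns (possibly with
#'   negative entries).
#' @export
inversion_estimate <- function(counts, model, dense_limit = 12L) {
  counts <- as_pattern_counts(counts)
  M <- full_transition_matrix(counts$n, model, dense_limit)
  phi <- stats::setNames(numeric(2^counts$n), rownames(M))
  phi[counts$patterns] <- counts$counts / counts$N
  stats::setNames(drop(phi %*% solve(M)), rownames(M))
}
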