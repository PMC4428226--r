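#' Bisulphite conversion and sequencing error model
#'
#' The two error sources of bisulphite amplicon sequencing are combined per
#' CpG site.  An unmethylated cytosine fails to convert with probability
#' `epsilon`, in which case it registers as methylated; methylated cytosines
#' are never converted, so non-conversion only moves 0 -> 1.  Independently,
#' the sequencing read flips the registered state of site `s` in either
#' direction with probability `eta[s]`.  Both rates are typically of order
#' 1e-2; a scalar `eta` is broadcast to all sites.
#'
#' @param epsilon Non-conversion probability, in `[0, 1)`.
#' @param eta Per-site sequencing error probability: scalar or length-`n`
#'   vector, each in `[0, 0.5)`.  Values above 0.1 trigger a warning.
#' @return Object of class `"error_model"` with elements `epsilon` and `eta`.
#' @examples
#' error_model(0.005, c(0.008, 0.006, 0.006, 0.006, 0.006, 0.008))
#' site_error_matrix(0.05, 0.02)
#' @seealso [site_error_matrix()], [full_transition_matrix()],
#'   [read_distribution()]
#' @export
error_model <- function(epsilon = 0, eta = 0) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("'epsilon' must be a single probability in [0, 1)")
  eta <- as.numeric(eta)
  if (length(eta) < 1L || anyNA(eta) || any(eta < 0) || any(eta >= 0.5))
    stop("'eta' must be probabilities in [0, 0.5)")
  if (epsilon > 0.1 || any(eta > 0.1))
    warning("error rates above 0.1 are implausibly large for bisulphite data")
  structure(list(epsilon = as.numeric(epsilon), eta = eta),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("Error model: epsilon =", format(x$epsilon),
      "; eta =", paste(format(x$eta), collapse = ", "),
      if (length(x$eta) == 1L) "(uniform across sites)", "\n")
  invisible(x)
}

# eta vector broadcast to n sites, with a dimension check.
eta_vector <- function(model, n) {
  eta <- model$eta
  if (length(eta) == 1L) return(rep(eta, n))
  if (length(eta) != n)
    stop("length of 'eta' (", length(eta), ") does not match n = ", n)
  eta
}

#' Per-site error matrix
#'
#' The 2x2 row-stochastic matrix of conditional probabilities that a site
#' with true state k (row) registers as state l (column), with rows/columns
#' labelled 0 (unmethylated) and 1 (methylated).  It is the product of the
#' conversion matrix `[[1-eps, eps], [0, 1]]` and the symmetric read-error
#' matrix `[[1-eta, eta], [eta, 1-eta]]`:
#' `[[1-eps-eta+2*eps*eta, eps+eta-2*eps*eta], [eta, 1-eta]]`.
#'
#' @param epsilon Non-conversion probability in `[0, 1)`.
#' @param eta_s Sequencing error probability at this site, in `[0, 0.5)`.
#' @return A 2x2 matrix with dimnames `c("0", "1")`.
#' @export
site_error_matrix <- function(epsilon, eta_s) {
  if (length(epsilon) != 1L || is.na(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("'epsilon' must be a single probability in [0, 1)")
  if (length(eta_s) != 1L || is.na(eta_s) || eta_s < 0 || eta_s >= 0.5)
    stop("'eta_s' must be a single probability in [0, 0.5)")
  matrix(c(1 - epsilon - eta_s + 2 * epsilon * eta_s, eta_s,
           epsilon + eta_s - 2 * epsilon * eta_s,     1 - eta_s),
         2L, 2L, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Probability that one pattern registers as another
#'
#' The pattern-level misclassification probability is the product over sites
#' of the per-site [site_error_matrix()] entries, i.e. an entry of the
#' Kronecker product `E_1 (x) ... (x) E_n` without materialising it.
#'
#' @param k True pattern: string, 0/1 vector, or integer index (with `n`).
#' @param l Registered pattern, in the same form.
#' @param model An [error_model()].
#' @param n Number of sites; required only when `k`/`l` are integer indices.
#' @return The probability that a read with true pattern `k` is observed as
#'   pattern `l`.
#' @export
transition_prob <- function(k, l, model, n = NULL) {
  kb <- index_or_pattern(k, n)
  lb <- index_or_pattern(l, n)
  if (length(kb) != length(lb))
    stop("'k' and 'l' have different numbers of sites")
  eta <- eta_vector(model, length(kb))
  p <- 1
  for (s in seq_along(kb)) {
    E <- site_error_matrix(model$epsilon, eta[s])
    p <- p * E[kb[s] + 1L, lb[s] + 1L]
  }
  p
}

# Accept an integer index (needs n) or a pattern; return 0/1 states.
index_or_pattern <- function(x, n) {
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.null(n)) return(pattern_states(decode_pattern(x, n)))
    if (!x %in% c(0, 1))
      stop("'n' is required when patterns are given as integer indices")
  }
  pattern_states(x)
}

#' Dense pattern-level transition matrix
#'
#' The full `2^n x 2^n` row-stochastic matrix `M` with `M[k, l]` the
#' probability that true pattern `k` registers as pattern `l`; the Kronecker
#' product of the per-site error matrices.  Rows and columns are labelled by
#' pattern strings in lexicographic (index) order.
#'
#' @param n Number of CpG sites.
#' @param model An [error_model()].
#' @param dense_limit Refuse to materialise the matrix for `n` above this
#'   (default 12); use [transition_prob()] entrywise instead.
#' @return A `2^n x 2^n` matrix.
#' @export
full_transition_matrix <- function(n, model, dense_limit = 12L) {
  if (n > dense_limit)
    stop("n = ", n, " exceeds the dense limit (", dense_limit, "); ",
         "evaluate entries on demand with transition_prob()")
  eta <- eta_vector(model, n)
  M <- Reduce(kronecker,
              lapply(eta, function(h) site_error_matrix(model$epsilon, h)))
  pats <- all_patterns(n)
  dimnames(M) <- list(pats, pats)
  M
}

# Misclassification sub-matrix between two pattern sets, built per site
# (never materialises the 2^n x 2^n Kronecker product).  Rows: 'from'
# (true) patterns; columns: 'to' (registered) patterns.
transition_submatrix <- function(from, to, model) {
  A <- pattern_bit_matrix(from)
  B <- pattern_bit_matrix(to)
  if (ncol(A) != ncol(B)) stop("pattern sets have different site counts")
  eta <- eta_vector(model, ncol(A))
  M <- matrix(1, nrow(A), nrow(B), dimnames = list(from, to))
  for (s in seq_len(ncol(A))) {
    E <- site_error_matrix(model$epsilon, eta[s])
    M <- M * E[cbind(rep(A[, s] + 1L, times = nrow(B)),
                     rep(B[, s] + 1L, each = nrow(A)))]
  }
  M
}

#' Validate a pattern frequency distribution
#'
#' A pattern distribution is a named numeric vector of probabilities over
#' pattern strings (a point on the `(2^n - 1)`-simplex; patterns absent from
#' the vector carry probability zero).
#'
#' @param theta Named numeric vector of pattern probabilities.
#' @param tol Tolerance on `sum(theta) == 1` (default 1e-6).
#' @return `theta`, invisibly, after validation.
#' @export
validate_distribution <- function(theta, tol = 1e-6) {
  if (is.null(names(theta)) || any(names(theta) == ""))
    stop("'theta' must be a named vector (names are pattern strings)")
  lens <- nchar(names(theta))
  if (any(lens != lens[1L])) stop("pattern names have unequal lengths")
  if (any(grepl("[^01]", names(theta)))) stop("pattern names must be binary strings")
  if (anyDuplicated(names(theta))) stop("duplicated patterns in 'theta'")
  if (anyNA(theta) || any(theta < 0)) stop("'theta' has negative or missing entries")
  if (abs(sum(theta) - 1) > tol)
    stop("'theta' must sum to 1 (got ", format(sum(theta)), ")")
  invisible(theta)
}

#' Push a pattern distribution through the error model
#'
#' Computes the registered-read distribution `phi`, with
#' `phi[l] = sum_k theta[k] * M[k, l]` over all `2^n` patterns.  With zero
#' error rates `phi` equals `theta`; with `eta = 0`, mass can only move from
#' a pattern to patterns methylated at a superset of its sites, because
#' methylated sites never convert.
#'
#' @param theta Named pattern distribution (see [validate_distribution()]).
#' @param model An [error_model()].
#' @param tol Validation tolerance for `theta`.
#' @return Named distribution over all `2^n` patterns.
#' @export
read_distribution <- function(theta, model, tol = 1e-6) {
  validate_distribution(theta, tol)
  n <- nchar(names(theta)[1L])
  support <- names(theta)[theta > 0]
  M <- transition_submatrix(support, all_patterns(n), model)
  phi <- drop(crossprod(M, theta[support]))
  phi / sum(phi)
}
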