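#' Simulate bisulphite amplicon reads from a pattern distribution
#'
#' Generates a synthetic pattern count table with exactly the error
#' structure the estimator assumes.  `n_reads` true patterns are drawn from
#' `theta` (multinomial); each read is then corrupted site by site: an
#' unmethylated site fails to convert (registers methylated) with
#' probability `epsilon`, after which the registered state flips with the
#' per-site sequencing error probability `eta[s]`.  Conversion error is
#' applied before read error, matching the order in which the per-site
#' error matrix is composed.  The result is distributed as a single
#' multinomial draw from `phi = theta %*% M` (see [read_distribution()]);
#' `method = "multinomial"` draws that way directly, which is faster for
#' large `n_reads` but does not retain read-level truth.
#'
#' @param theta Named true pattern distribution (see
#'   [validate_distribution()]).
#' @param n_reads Number of reads to simulate.
#' @param model An [error_model()].
#' @param seed Optional integer seed; when given, the simulation is
#'   reproducible bit for bit and the caller's RNG state is restored on
#'   exit.
#' @param method `"per_read"` (default) corrupts each read site-wise and
#'   retains the latent true pattern of every read; `"multinomial"` draws
#'   observed counts directly from `phi` (requires `n <= 16`).
#' @return An object of class `"pattern_sim"`: a list with
#'   \describe{
#'     \item{counts}{[pattern_counts()] of observed (registered) patterns.}
#'     \item{true_counts}{[pattern_counts()] of latent true patterns
#'       (`NULL` for `method = "multinomial"`).}
#'     \item{theta, model, n_reads, seed, method}{the simulation spec.}
#'   }
#' @examples
#' theta <- c("00" = 0.5, "11" = 0.5)
#' sim <- simulate_reads(theta, 1000, error_model(0.05, 0.02), seed = 1)
#' sim$counts
#' @export
simulate_reads <- function(theta, n_reads, model, seed = NULL,
                           method = c("per_read", "multinomial")) {
  method <- match.arg(method)
  validate_distribution(theta)
  if (length(n_reads) != 1L || n_reads < 1 || n_reads != trunc(n_reads))
    stop("'n_reads' must be a single positive integer")
  stopifnot(inherits(model, "error_model"))
  n <- nchar(names(theta)[1L])
  eta <- eta_vector(model, n)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    rng_state <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", rng_state, envir = globalenv()))
    set.seed(seed)
  }

  support <- names(theta)[theta > 0]
  true_y <- drop(stats::rmultinom(1L, n_reads, theta[support]))
  names(true_y) <- support
  true_counts <- pattern_counts(support[true_y > 0], true_y[true_y > 0])

  if (method == "multinomial") {
    phi <- read_distribution(theta, model)
    obs <- drop(stats::rmultinom(1L, n_reads, phi))
    names(obs) <- names(phi)
    counts <- pattern_counts(names(obs)[obs > 0], obs[obs > 0])
    true_counts <- NULL
  } else {
    bits <- pattern_bit_matrix(support)[rep(seq_along(support), true_y), ,
                                        drop = FALSE]
    # non-conversion: 0 -> 1 with prob epsilon, methylated sites unaffected
    flip0 <- matrix(stats::runif(length(bits)) < model$epsilon,
                    nrow(bits), n)
    registered <- ifelse(bits == 0L & flip0, 1L, bits)
    # symmetric per-site read error
    fliperr <- matrix(stats::runif(length(bits)) <
                        rep(eta, each = nrow(bits)), nrow(bits), n)
    observed <- (registered + fliperr) %% 2
    pats <- do.call(paste0, as.data.frame(observed))
    tab <- table(pats)
    counts <- pattern_counts(names(tab), as.integer(tab))
  }
  structure(list(counts = counts, true_counts = true_counts, theta = theta,
                 model = model, n_reads = as.integer(n_reads), seed = seed,
                 method = method),
            class = "pattern_sim")
}

#' @export
print.pattern_sim <- function(x, ...) {
  cat(sprintf("Simulated reads: N_read = %d, %d observed patterns (%s)\n",
              x$n_reads, length(x$counts$patterns), x$method))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  print(x$counts)
  invisible(x)
}

#' Truncate a pattern distribution at a frequency floor
#'
#' Sets components below `floor` to zero and renormalises the remainder to
#' sum to one.  Used to build sparse "true" distributions for simulation
#' studies from a dense initial estimate.
#'
#' @param theta Named pattern distribution.
#' @param floor Frequency below which components are zeroed, in `[0, 1)`.
#' @return The truncated, renormalised distribution.
#' @export
truncate_distribution <- function(theta, floor = 0.005) {
  validate_distribution(theta)
  if (length(floor) != 1L || floor < 0 || floor >= 1)
    stop("'floor' must be a single probability in [0, 1)")
  theta[theta < floor] <- 0
  if (sum(theta) <= 0)
    stop("all components fall below the floor; the distribution is degenerate")
  theta / sum(theta)
}

#' Worked six-site synthetic dataset
#'
#' A reference dataset for a locus with `n = 6` CpG sites: a sparse true
#' distribution over 6 patterns (mimicking a mix of high- and low-abundance
#' epialleles), 2000 reads redistributed by non-conversion
#' (`epsilon = 0.005`) and sequencing error
#' (`eta = c(0.008, 0.006, 0.006, 0.006, 0.006, 0.008)`, degrading towards
#' the read ends), giving 24 observed patterns of which 18 are spurious.
#' `reference` also records previously published frequency estimates for
#' the same counts (slow and fast mode) for regression comparison.
#'
#' @return A list with elements `theta` (named true distribution), `counts`
#'   ([pattern_counts()]), `model` ([error_model()]) and `reference`
#'   (data frame: `pattern`, `theta`, `y`, `y_over_N`, `theta_slow`,
#'   `theta_fast`).
#' @export
table1_fixture <- function() {
  ref <- data.frame(
    pattern = c("000000", "000001", "000010", "000100", "001000", "001001",
                "001010", "001100", "010000", "011000", "011011", "011101",
                "011111", "100000", "101101", "101111", "110000", "110111",
                "111001", "111011", "111100", "111101", "111110", "111111"),
    theta = c(0.5, 0, 0, 0, 0.04, 0, 0, 0, 0, 0, 0, 0,
              0.03, 0.03, 0, 0, 0, 0, 0, 0, 0, 0.2, 0, 0.2),
    y = c(907L, 15L, 8L, 7L, 99L, 4L, 1L, 1L, 6L, 2L, 1L, 2L,
          63L, 77L, 1L, 1L, 1L, 2L, 1L, 1L, 3L, 393L, 3L, 401L),
    theta_slow = c(0.4813, 0.0013, 0, 0, 0.0466, 0.0016, 0, 0, 0, 0.0007,
                   0.0005, 0, 0.0308, 0.0328, 0, 0, 0, 0, 0, 0, 0,
                   0.2001, 0, 0.2044),
    theta_fast = c(0.4812, 0.0013, 0, 0, 0.0466, 0.0014, 0, 0, 0, 0.0004,
                   0.0002, 0, 0.0306, 0.0329, 0, 0, 0, 0, 0, 0, 0,
                   0.2013, 0, 0.2040),
    stringsAsFactors = FALSE)
  ref$y_over_N <- ref$y / sum(ref$y)
  ref <- ref[c("pattern", "theta", "y", "y_over_N", "theta_slow", "theta_fast")]
  list(theta = stats::setNames(ref$theta, ref$pattern),
       counts = pattern_counts(ref$pattern, ref$y),
       model = error_model(0.005, c(0.008, 0.006, 0.006, 0.006, 0.006, 0.008)),
       reference = ref)
}

#' Worked eight-site amplicon dataset
#'
#' Observed pattern counts from a bisulphite PCR amplicon of the honey bee
#' gene GB17113 (a 6-phosphofructokinase), sequenced on the 454 platform:
#' `n = 8` CpG sites, 36 patterns with non-zero reads, `N_read = 1793`.
#' The error rates conventionally applied to these data are
#' `epsilon = 0.01` and a uniform `eta = 0.02`.  The true distribution is
#' unknown (biological data), so there is no truth column.
#'
#' @return A list with elements `counts` ([pattern_counts()]) and `model`
#'   ([error_model()]).
#' @export
table2_fixture <- function() {
  pats <- c("00000000", "00000001", "00000010", "00000100", "00000110",
            "00001000", "00001001", "00001010", "00010000", "00010100",
            "00100000", "00100001", "00101000", "00110000", "01000000",
            "01000001", "01100000", "01100001", "01101000", "01110000",
            "01110100", "10000000", "10000001", "10000010", "10000100",
            "10001000", "10010000", "10010100", "10100000", "11000100",
            "11010000", "11100000", "11100100", "11110000", "11110100",
            "11110110")
  y <- c(1265L, 52L, 32L, 40L, 3L, 75L, 1L, 2L, 36L, 10L, 31L, 2L, 1L, 1L,
         20L, 1L, 39L, 4L, 1L, 1L, 1L, 84L, 2L, 5L, 14L, 1L, 2L, 8L, 2L,
         1L, 1L, 1L, 2L, 2L, 42L, 8L)
  list(counts = pattern_counts(pats, y),
       model = error_model(0.01, 0.02))
}
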