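test_that("with zero error rates the MLE is the naive multinomial estimate", {
  set.seed(101)
  for (n in c(2L, 5L, 8L)) {
    counts <- random_counts(n, min(2^n, 12L), 500L)
    fit <- estimate_patterns(counts, epsilon = 0, eta = 0)
    y <- counts$counts[counts$counts > 0]
    expect_equal(as.numeric(coef(fit)), y / counts$N, tolerance = 1e-12)
    expect_length(spurious_patterns(fit), 0L)
    if (n <= 8L) {
      slow <- estimate_patterns(counts, epsilon = 0, eta = 0, mode = "slow")
      obs <- names(naive_estimate(counts))
      expect_equal(as.numeric(coef(slow)[obs]), y / counts$N,
                   tolerance = 1e-12)
      expect_true(all(coef(slow)[setdiff(names(coef(slow)), obs)] == 0))
      expect_length(spurious_patterns(slow), 0L)
    }
  }
})

test_that("the log-likelihood matches the dense-matrix oracle", {
  counts <- pattern_counts(c("00", "01", "10", "11"), c(10L, 5L, 3L, 2L))
  mod <- error_model(0.05, 0.02)
  th <- c("00" = 0.25, "01" = 0.25, "10" = 0.25, "11" = 0.25)
  y <- stats::setNames(counts$counts, counts$patterns)
  expect_equal(pattern_loglik(th, counts, mod),
               oracle_loglik(rep(0.25, 4), y, 0.05, 0.02, 2),
               tolerance = 1e-12)
  # identity model: multinomial log-likelihood at y/N
  expect_equal(pattern_loglik(y / 20, counts, error_model(0, 0)),
               sum(y * log(y / 20)), tolerance = 1e-12)
  # a point mass that gives an observed pattern zero probability
  expect_identical(pattern_loglik(c("11" = 1), counts, error_model(0, 0)),
                   -Inf)
})

test_that("the optimiser attains the maximum found by dense random search", {
  set.seed(202)
  cases <- list(
    list(n = 2L, y = c("00" = 10, "01" = 5, "10" = 3, "11" = 2),
         eps = 0.05, eta = 0.02),
    list(n = 2L, y = c("00" = 120, "11" = 60, "01" = 3),
         eps = 0.01, eta = 0.015),
    list(n = 3L, y = c("000" = 80, "011" = 25, "111" = 40, "100" = 2,
                       "001" = 1), eps = 0.02, eta = 0.01))
  for (cs in cases) {
    counts <- pattern_counts(names(cs$y), cs$y)
    fit <- estimate_patterns(counts, epsilon = cs$eps, eta = cs$eta,
                             mode = "slow")
    # 1e5 Dirichlet(1) points over the full simplex
    pts <- runif_simplex(1e5L, 2^cs$n)
    M <- oracle_dense_M(cs$eps, cs$eta, cs$n)
    idx <- match(names(cs$y), oracle_patterns(cs$n))
    phi <- pts %*% M[, idx, drop = FALSE]
    search_best <- max(log(phi) %*% cs$y)
    expect_gte(fit$logLik, search_best - 1e-6)
  }
})

test_that("the constrained MLE is unique: restarts agree componentwise", {
  set.seed(303)
  fx <- table1_fixture()
  y <- naive_estimate(fx$counts) * fx$counts$N
  reference <- estimate_patterns(fx$counts, model = fx$model)
  M <- epifreq:::transition_submatrix(names(y), names(y), fx$model)
  for (i in 1:10) {
    th0 <- drop(runif_simplex(1, length(y)))
    names(th0) <- names(y)
    fit <- epifreq:::em_maximise(th0, M, y, tol = 1e-10, max_iter = 1e5L)
    refined <- boundary_refine(stats::setNames(fit$theta, names(y)),
                               fx$counts, fx$model)
    expect_equal(as.numeric(refined), as.numeric(coef(reference)),
                 tolerance = 1e-5)
  }
})

test_that("for n = 1 the estimator matches the closed-form binomial MLE", {
  closed_form <- function(y0, y1, eps, eta) {
    E <- oracle_site_matrix(eps, eta)
    N <- y0 + y1
    theta <- drop((c(y0, y1) / N) %*% solve(E))
    if (all(theta >= 0)) return(theta)
    ll <- function(th) {
      phi <- drop(th %*% E)
      if (any(phi == 0 & c(y0, y1) > 0)) return(-Inf)
      sum(c(y0, y1)[c(y0, y1) > 0] * log(phi[c(y0, y1) > 0]))
    }
    if (ll(c(1, 0)) >= ll(c(0, 1))) c(1, 0) else c(0, 1)
  }
  grid <- expand.grid(y0 = c(990, 500, 20, 3), y1 = c(10, 480, 0),
                      eps = c(0.01, 0.05), eta = c(0, 0.02))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$y0 + g$y1 == 0) next
    counts <- pattern_counts(c("0", "1"), c(g$y0, g$y1))
    fit <- estimate_patterns(counts, epsilon = g$eps, eta = g$eta,
                             mode = "slow")
    expect_equal(as.numeric(coef(fit)[c("0", "1")]),
                 closed_form(g$y0, g$y1, g$eps, g$eta), tolerance = 1e-6,
                 label = sprintf("y=(%d,%d) eps=%g eta=%g",
                                 g$y0, g$y1, g$eps, g$eta))
  }
})

test_that("with eta = 0 the reported support shrinks and methylation skews down", {
  set.seed(404)
  theta <- c("00000" = 0.55, "00111" = 0.2, "11111" = 0.2, "10000" = 0.05)
  mod <- error_model(0.04, 0)
  sim <- simulate_reads(theta, 3000L, mod, seed = 17L)
  fit <- estimate_patterns(sim$counts, model = mod, mode = "slow")
  obs <- names(naive_estimate(sim$counts))
  support <- names(coef(fit))[coef(fit) > 0]
  expect_true(all(support %in% obs))
  mean_meth <- function(p) {
    sum(p * vapply(names(p), methylation_count, 1L))
  }
  expect_lte(mean_meth(coef(fit)[coef(fit) > 0]),
             mean_meth(naive_estimate(sim$counts)) + 1e-12)
})

test_that("simulated data recover the generating distribution (L1)", {
  fx <- table1_fixture()
  failures <- 0L
  for (rep in 1:10) {
    sim <- simulate_reads(fx$theta, 1e5L, fx$model, seed = 1000L + rep,
                          method = "multinomial")
    fit <- estimate_patterns(sim$counts, model = fx$model)
    est <- stats::setNames(numeric(length(fx$theta)), names(fx$theta))
    common <- intersect(names(coef(fit)), names(est))
    est[common] <- coef(fit)[common]
    l1 <- sum(abs(est - fx$theta)) + sum(coef(fit)[setdiff(names(coef(fit)),
                                                           names(est))])
    expect_lt(l1, 0.05)  # loose per-replicate sanity bound
    if (l1 >= 0.02) failures <- failures + 1L
  }
  expect_lte(failures, 1L)
})

test_that("fast and slow modes agree on the worked six-site table", {
  fx <- table1_fixture()
  fast <- estimate_patterns(fx$counts, model = fx$model, mode = "fast")
  slow <- estimate_patterns(fx$counts, model = fx$model, mode = "slow")
  obs <- names(naive_estimate(fx$counts))
  expect_lt(max(abs(coef(fast)[obs] - coef(slow)[obs])), 0.002)
  # slow mode puts essentially no mass on unobserved patterns here
  expect_lt(sum(coef(slow)[setdiff(names(coef(slow)), obs)]), 1e-8)
})

test_that("boundary refinement snaps only when the likelihood allows it", {
  counts <- pattern_counts(c("00", "01", "11"), c(50L, 30L, 20L))
  mod <- error_model(0.02, 0.01)
  fit <- estimate_patterns(counts, model = mod)
  # strictly interior solution: refinement returns it unchanged
  expect_identical(boundary_refine(coef(fit), counts, mod), coef(fit))
  # a negligible component whose removal does not hurt the likelihood
  theta <- coef(fit)[coef(fit) > 0]
  theta <- c(theta * (1 - 1e-12), "10" = 1e-12)
  refined <- boundary_refine(theta[order(names(theta), method = "radix")],
                             counts, mod)
  expect_identical(refined[["10"]], 0)
  expect_equal(sum(refined), 1, tolerance = 1e-12)
})

test_that("guards: slow mode for large n and fast mode for many patterns", {
  counts <- pattern_counts(strrep(c("0", "1"), 9L), c(5L, 5L))
  expect_error(estimate_patterns(counts, mode = "slow"), "n > 8")
  set.seed(9)
  big <- random_counts(10L, 250L, 5000L)
  expect_warning(estimate_patterns(big, epsilon = 0, eta = 0), "observed patterns")
})
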