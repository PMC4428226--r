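test_that("the per-site error matrix matches its closed form", {
  expect_equal(site_error_matrix(0, 0), diag(2), ignore_attr = TRUE)
  expect_equal(site_error_matrix(0.05, 0.02),
               matrix(c(0.932, 0.02, 0.068, 0.98), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-15)
  # with no read error only the conversion matrix remains
  expect_equal(site_error_matrix(0.01, 0),
               matrix(c(0.99, 0, 0.01, 1), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_error(site_error_matrix(1, 0), "epsilon")
  expect_error(site_error_matrix(0.1, 0.5), "eta")
})

test_that("error_model validates and broadcasts rates", {
  m <- error_model(0.005, 0.006)
  expect_identical(epifreq:::eta_vector(m, 4L), rep(0.006, 4L))
  mv <- error_model(0.01, c(0.02, 0.03))
  expect_identical(epifreq:::eta_vector(mv, 2L), c(0.02, 0.03))
  expect_error(epifreq:::eta_vector(mv, 3L), "does not match")
  expect_error(error_model(-0.1, 0), "epsilon")
  expect_warning(error_model(0.2, 0.01), "implausibly large")
})

test_that("transition probabilities equal Kronecker-product entries", {
  expect_identical(transition_prob("01", "01", error_model(0, 0)), 1)
  expect_identical(transition_prob("01", "10", error_model(0, 0)), 0)
  m <- error_model(0.05, 0.02)
  expect_equal(transition_prob(c(0, 0), c(1, 0), m), 0.068 * 0.932,
               tolerance = 1e-15)
  # entrywise against the dense kronecker oracle, several models
  set.seed(42)
  for (n in c(1L, 2L, 4L)) {
    eps <- runif(1, 0, 0.05)
    eta <- runif(n, 0, 0.05)
    M <- oracle_dense_M(eps, eta, n)
    mod <- error_model(eps, eta)
    for (k in seq_len(2^n))
      for (l in seq_len(2^n))
        expect_equal(transition_prob(k, l, mod, n = n), M[k, l],
                     tolerance = 1e-13)
  }
  expect_error(transition_prob("01", "011", error_model(0, 0)),
               "different numbers of sites")
})

test_that("the dense transition matrix is row-stochastic and consistent", {
  m1 <- error_model(0.03, 0.01)
  expect_equal(full_transition_matrix(1, m1), site_error_matrix(0.03, 0.01),
               ignore_attr = TRUE)
  expect_equal(full_transition_matrix(3, error_model(0, 0)), diag(8),
               ignore_attr = TRUE)
  set.seed(7)
  for (n in c(2L, 5L, 8L)) {
    mod <- error_model(runif(1, 0, 0.05), runif(n, 0, 0.05))
    M <- full_transition_matrix(n, mod)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    expect_true(all(M >= 0))
    expect_lt(max(abs(rowSums(site_error_matrix(mod$epsilon, mod$eta[1])) - 1)),
              1e-12)
  }
  expect_error(full_transition_matrix(13, m1), "dense limit")
})

test_that("implicit submatrix evaluation agrees with the dense matrix", {
  set.seed(19)
  for (n in c(2L, 6L, 8L)) {
    mod <- error_model(runif(1, 0, 0.03), runif(n, 0, 0.03))
    pats <- oracle_patterns(n)
    Md <- oracle_dense_M(mod$epsilon, mod$eta, n)
    sub_from <- sample(2^n, min(10L, 2^n))
    sub_to <- sample(2^n, min(12L, 2^n))
    Ms <- epifreq:::transition_submatrix(pats[sub_from], pats[sub_to], mod)
    expect_equal(Ms, Md[sub_from, sub_to, drop = FALSE],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("without read error, mass never moves off a methylated site", {
  # eta = 0: a read can only gain methylated states (non-conversion is 0->1),
  # so M[k, l] = 0 whenever l is unmethylated at a site where k is methylated
  n <- 6L
  mod <- error_model(0.02, 0)
  M <- full_transition_matrix(n, mod)
  pats <- rownames(M)
  bits <- epifreq:::pattern_bit_matrix(pats)
  for (k in seq_len(2^n)) {
    loses_one <- apply(bits, 1L, function(l) any(bits[k, ] == 1L & l == 0L))
    expect_true(all(M[k, loses_one] == 0))
    expect_true(all(M[k, !loses_one] > 0))
  }
})

test_that("read_distribution pushes theta through the model and conserves mass", {
  m0 <- error_model(0, 0)
  th <- c("00" = 0.25, "01" = 0.25, "10" = 0.25, "11" = 0.25)
  expect_equal(read_distribution(th, m0), th)
  # all-ones point mass is invariant under pure non-conversion
  m_eps <- error_model(0.07, 0)
  phi <- read_distribution(c("111" = 1), m_eps)
  expect_equal(phi[["111"]], 1)
  expect_equal(sum(phi), 1, tolerance = 1e-12)
  # dense matrix-vector oracle
  mod <- error_model(0.05, 0.02)
  phi2 <- read_distribution(th, mod)
  expect_equal(as.numeric(phi2),
               drop(rep(0.25, 4) %*% oracle_dense_M(0.05, 0.02, 2)),
               tolerance = 1e-12)
  # conservation for random simplex points
  set.seed(3)
  for (i in 1:5) {
    theta <- drop(runif_simplex(1, 8))
    names(theta) <- oracle_patterns(3)
    expect_equal(sum(read_distribution(theta, mod)), 1, tolerance = 1e-10)
  }
  expect_error(read_distribution(c("00" = 0.9), mod), "sum to 1")
})
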