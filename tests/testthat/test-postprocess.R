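# a minimal fit-like object with given draws (J countries, T years)
fake_fit <- function(draws_a, draws_b, draws_u, draws_psi, draws_phi = NULL,
                     J, T, knots = c(45, 60), center = 50) {
  list(J = J, T = T, knots = knots, age_center = center,
       t_center = (T + 1) / 2,
       combined = list(a = draws_a, b = draws_b, u = draws_u,
                       psi = draws_psi, phi = draws_phi))
}

test_that("zero draws predict prevalence one half everywhere", {
  J <- 2; T <- 3; nd <- 4
  fit <- fake_fit(matrix(0, nd, J), matrix(0, nd, J), matrix(0, nd, J * T),
                  matrix(0, nd, 5 * J), matrix(0, nd, 5 * J), J, T)
  surf <- predict_prevalence_draws(fit, mid_ages = c(30, 60))
  expect_true(all(surf == 0.5))
  expect_equal(dim(surf), c(nd, J, T, 2))
  expect_error(predict_prevalence_draws(fit, 30, years = 9), "outside")
})

test_that("predictions equal the latent-mean composition on random draws", {
  set.seed(6)
  J <- 3; T <- 4; nd <- 5
  a <- matrix(rnorm(nd * J, -1, 0.2), nd)
  b <- matrix(rnorm(nd * J, 0, 0.01), nd)
  u <- matrix(rnorm(nd * J * T, 0, 0.05), nd)
  psi <- matrix(rnorm(nd * 5 * J, 0, 0.001), nd)
  phi <- matrix(rnorm(nd * 5 * J, 0, 1e-4), nd)
  fit <- fake_fit(a, b, u, psi, phi, J, T)
  ages <- c(35, 55)
  surf <- predict_prevalence_draws(fit, ages)
  B <- age_spline_basis(ages, c(45, 60), 50)
  for (d in 1:nd) for (j in 1:J) for (t in 1:T) for (h in 1:2) {
    tc <- t - (T + 1) / 2
    m <- a[d, j] + b[d, j] * tc + u[d, (j - 1) * T + t] +
      sum(B[h, ] * psi[d, (j - 1) * 5 + 1:5]) +
      sum(B[h, ] * phi[d, (j - 1) * 5 + 1:5]) * tc
    expect_equal(unname(surf[d, j, t, h]), pnorm(m), tolerance = 1e-12)
  }
})

test_that("rescaling divides by the category sum and extracts obesity", {
  dims <- c(2, 1, 1, 1)
  mk <- function(x) array(x, dims)
  surfaces <- list("25to30" = mk(0.9), "30to35" = mk(0.06),
                   "35to40" = mk(0.03), "gte40" = mk(0.01))
  out <- rescale_and_obesity(surfaces)
  expect_equal(as.vector(out$obesity), rep(0.10, 2), tolerance = 1e-12)
  expect_true(all(abs(apply(out$rescaled, 1:4, sum) - 1) < 1e-12))
  expect_equal(as.vector(out$scaling), rep(1, 2), tolerance = 1e-12)
  # raw sum 0.8: every category multiplied by 1.25
  surfaces2 <- list("25to30" = mk(0.7), "30to35" = mk(0.1))
  out2 <- rescale_and_obesity(surfaces2, obesity_categories = "30to35")
  expect_equal(as.vector(out2$scaling), rep(1.25, 2))
  expect_equal(as.vector(out2$rescaled[, , , , 1]), rep(0.875, 2))
  # rescaling preserves within-cell category ranking
  expect_true(all(out2$rescaled[, , , , 1] > out2$rescaled[, , , , 2]))
  surfaces3 <- list(a = mk(0), b = mk(0))
  expect_error(rescale_and_obesity(surfaces3, obesity_categories = "a"),
               "not positive")
})

test_that("age standardization is a weighted mean and linear", {
  surf <- array(0, c(2, 1, 1, 2))
  surf[, , , 1] <- 0.10; surf[, , , 2] <- 0.30
  std <- standard_population(1:2, c(0.25, 0.75))
  expect_equal(as.vector(age_standardize(surf, std)), rep(0.25, 2))
  # weight concentrated on one band returns that band
  std1 <- standard_population(1:2, c(1, 0))
  expect_equal(as.vector(age_standardize(surf, std1)), rep(0.10, 2))
  # equal weights give the arithmetic mean
  stdE <- standard_population(1:2, c(1, 1))
  expect_equal(as.vector(age_standardize(surf, stdE)), rep(0.20, 2))
  # linearity
  surfB <- surf * 0.5 + 0.1
  lhs <- age_standardize(0.3 * surf + 0.7 * surfB, std)
  rhs <- 0.3 * age_standardize(surf, std) + 0.7 * age_standardize(surfB, std)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # missing weight for a labelled band is an error
  dimnames(surf)[[4]] <- c("20-24", "25-29")
  expect_error(age_standardize(surf, standard_population("20-24", 1)), "25-29")
})

test_that("velocity is the signed year-on-year difference in pp", {
  s <- array(rep(c(0.10, 0.12, 0.11), each = 2), c(2, 1, 3),
             dimnames = list(NULL, NULL, 2001:2003))
  v <- velocity_series(s)
  expect_equal(as.vector(v[1, 1, ]), c(2, -1))
  expect_equal(dimnames(v)[[3]], c("2002", "2003"))
  # constant series has zero velocity
  sc <- array(0.2, c(3, 2, 4))
  expect_true(all(velocity_series(sc) == 0))
  # telescoping: per draw, velocities sum to the endpoint difference
  set.seed(9)
  sr <- array(runif(2 * 3 * 6), c(2, 3, 6))
  vr <- velocity_series(sr)
  expect_equal(apply(vr, 1:2, sum), 100 * (sr[, , 6] - sr[, , 1]),
               tolerance = 1e-9)
})

test_that("posterior summaries use order statistics and strict positivity", {
  s <- posterior_summaries(c(-1, 1, 1, 1))
  expect_equal(s$pp_positive, 0.75)
  expect_equal(posterior_summaries(c(2, 3))$pp_positive, 1)
  expect_equal(posterior_summaries(c(0, 1))$pp_positive, 0.5) # zero not positive
  set.seed(12)
  z <- rnorm(5000)
  s2 <- posterior_summaries(z)
  expect_lt(abs(s2$lower + 1.96), 0.05)
  expect_lt(abs(s2$upper - 1.96), 0.05)
  expect_error(posterior_summaries(numeric(0)), "no draws")
})

test_that("the bundled standard population normalizes and restricts", {
  std <- who_standard_population()
  expect_equal(sum(std$weight), 1, tolerance = 1e-12)
  adult <- who_standard_population(min_age = 20)
  expect_equal(sum(adult$weight), 1, tolerance = 1e-12)
  expect_false("0-4" %in% adult$age_group)
  expect_true("85plus" %in% adult$age_group)
})

test_that("scaling factors stay near one on model-generated category sets", {
  # a calibrated seven-category world: global intercepts are probit transforms
  # of prevalences that sum to one, so raw per-cell category sums are close
  # to one and rescaling is a small correction
  props <- c(0.035, 0.055, 0.40, 0.31, 0.12, 0.055, 0.025)
  cf <- simulation_config(J = 4, L = 2, M = 1, T = 6, mid_ages = c(35, 55),
                          n_categories = 7, ag_true = qnorm(props),
                          bg_true = 0,
                          kappa = c(ac = 4e-3, ar = 4e-3, as_ = 2e-3,
                                    bc = 1e-5, br = 1e-5, bs = 1e-5),
                          lambda = c(c = 1e6, r = 3e6, s = 9e6, g = 2.7e7),
                          psi_g_true = rep(0, 5), phi_g_true = rep(0, 5),
                          seed = 23)
  w <- generate_world(cf)
  raw <- attr(w$surfaces, "raw")
  # emulate posterior category surfaces: truth plus modest probit-scale noise
  set.seed(8)
  nd <- 40
  dims <- dim(raw)
  est <- array(NA_real_, c(nd, dims))
  for (d in seq_len(nd)) est[d, , , , ] <- pnorm(qnorm(raw) + rnorm(length(raw), 0, 0.03))
  dimnames(est) <- c(rep(list(NULL), 4), list(cf$category_labels))
  out <- rescale_and_obesity(est, obesity_categories = cf$category_labels[5:7])
  avg_scaling <- mean(out$scaling)
  expect_gt(avg_scaling, 0.95)
  expect_lt(avg_scaling, 1.05)
})
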