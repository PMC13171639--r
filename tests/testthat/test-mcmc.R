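`%||%` <- function(a, b) if (is.null(a)) b else a

fake_chain <- function(n, val = NULL) {
  structure(list(a = NULL, b = NULL, u = NULL, psi = NULL, phi = NULL,
                 hyper = matrix(val %||% rnorm(n), n, 1),
                 lp = rep(0, n)), class = "chain_draws")
}

hyper_vector_list <- function(states) lapply(states, function(s)
  c(s$ag, s$bg, log(s$tau2), log(s$lambda), log(s$v)))

test_that("split-Rhat behaves on iid, hand-sized and degenerate inputs", {
  set.seed(1)
  draws <- matrix(rnorm(40000), 10000, 4)
  r <- split_rhat(draws)
  expect_gt(r, 0.99); expect_lt(r, 1.02)
  # hand-sized input against a direct formula evaluation
  x <- matrix(c(1, 2, 3, 4, 2, 2, 4, 5), 4, 2)
  halves <- cbind(x[1:2, 1], x[3:4, 1], x[1:2, 2], x[3:4, 2])
  W <- mean(apply(halves, 2, var))
  B <- 2 * var(colMeans(halves))
  expected <- sqrt(((2 - 1) / 2 * W + B / 2) / W)
  expect_equal(as.numeric(split_rhat(x)), expected, tolerance = 1e-12)
  # constant chains return the sentinel rather than NaN
  const <- matrix(5, 100, 4)
  rc <- split_rhat(const)
  expect_equal(as.numeric(rc), 1)
  expect_true(isTRUE(attr(rc, "degenerate")))
  expect_error(split_rhat(matrix(1:10, 10, 1)), "at least 2 chains")
})

test_that("thinning is even, exact in count, and balanced across chains", {
  chains <- lapply(1:8, function(i) fake_chain(50000, val = rep(i, 50000)))
  comb <- thin_and_combine(chains, 5000)
  expect_equal(nrow(comb$hyper), 5000)
  expect_equal(unname(table(comb$chain)), rep(625L, 8), ignore_attr = TRUE)
  # target equal to total is the identity
  chains2 <- lapply(1:2, function(i) fake_chain(100))
  comb2 <- thin_and_combine(chains2, 200)
  expect_equal(comb2$hyper,
               rbind(chains2[[1]]$hyper, chains2[[2]]$hyper))
  # per-chain contribution differs by at most one
  comb3 <- thin_and_combine(lapply(1:3, function(i) fake_chain(100)), 100)
  tab <- table(comb3$chain)
  expect_lte(max(tab) - min(tab), 1)
  expect_error(thin_and_combine(chains2, 500), "insufficient")
})

test_that("conjugate single-level reduction matches the closed form", {
  toy <- conjugate_toy(seed = 2)
  fr <- toy$frame
  post <- conjugate_posterior(toy)
  st <- new_model_state(fr)
  st$tau2 <- toy$tau2
  st$v <- c(n = toy$v, s = toy$v * 2, c = toy$v * 4)
  st$alpha <- toy$alpha
  ctrl <- list(blocks = c("e", "linear"), fix_alpha = TRUE)
  n_iter <- 3000; burn <- 500
  a_draw <- b_draw <- numeric(n_iter - burn)
  e_draw <- matrix(0, n_iter - burn, toy$S)
  set.seed(11)
  for (it in seq_len(n_iter)) {
    st <- gibbs_sweep(st, fr, ctrl)
    if (it > burn) {
      k <- it - burn
      a_draw[k] <- st$ac[1] + st$ar[1] + st$as_[1] + st$ag
      b_draw[k] <- st$bc[1] + st$br[1] + st$bs[1] + st$bg
      e_draw[k, ] <- st$e
    }
  }
  expect_lt(abs(mean(a_draw) - post$mean[1]), 3 * bm_se(a_draw))
  expect_lt(abs(mean(b_draw) - post$mean[2]), 3 * bm_se(b_draw))
  for (s in 1:2) {
    expect_lt(abs(mean(e_draw[, s]) - post$mean[2 + s]), 3 * bm_se(e_draw[, s]))
  }
  # posterior variance of the composite intercept
  expect_equal(var(a_draw), post$cov[1, 1], tolerance = 0.15)
})

test_that("collapsed variance step recovers the marginal posterior of v", {
  # alpha fixed as data, only study effects random: the marginal posterior of
  # v_n is one-dimensional and integrable on a grid
  toy <- conjugate_toy(S = 12, rows_per = 3, T = 6, tau2 = 0.01, v = 0.03,
                       seed = 4)
  fr <- toy$frame
  st <- new_model_state(fr)
  st$tau2 <- toy$tau2
  st$alpha <- toy$alpha
  # suppress the blocks outside the oracle: smoothing precisions at the
  # truncation ceiling make u negligible, spline variances pinned near zero
  st$lambda[] <- exp(c(18.5, 19, 19.5, 19.9))
  st$sigma2_psi[] <- 1e-18
  st$sigma2_phi[] <- 1e-20
  ctrl <- list(blocks = c("e", "linear"), fix_alpha = TRUE)
  n_iter <- 4000; burn <- 1000
  v_draw <- numeric(n_iter - burn)
  set.seed(3)
  for (it in seq_len(n_iter)) {
    st <- gibbs_sweep(st, fr, ctrl)
    st <- mh_variance_step(st, fr, list(adapt = it <= burn, vars = "v"))
    if (it > burn) v_draw[it - burn] <- st$v[1]
  }
  # numeric oracle: integrate out (a*, b*, e) for each v on a grid; prior
  # weight for v_n includes the ordering volume (sqrt(cap)-sqrt(v))^2
  grid <- exp(seq(log(0.002), log(0.24), length.out = 160))
  cap <- st$caps$v
  loglik <- vapply(grid, function(v) {
    toy2 <- toy; toy2$v <- v
    post <- conjugate_posterior(toy2)
    Z <- post$Z
    # marginal likelihood of alpha with theta integrated out (flat a*, b*)
    Q <- crossprod(Z) / toy$tau2 + diag(c(0, 0, rep(1 / v, toy$S)))
    b <- crossprod(Z, toy$alpha) / toy$tau2
    0.5 * drop(t(b) %*% solve(Q, b)) - 0.5 * determinant(Q)$modulus -
      toy$S / 2 * log(v)
  }, 0.0)
  logpost <- loglik - 0.5 * log(grid) + 2 * log(sqrt(cap) - sqrt(grid))
  w <- exp(logpost - max(logpost)) * grid   # density on the log grid
  cdf <- cumsum(w) / sum(w)
  oracle_q <- approx(cdf, grid, xout = c(0.25, 0.5, 0.75))$y
  mcmc_q <- quantile(v_draw, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(mcmc_q, oracle_q, tolerance = 0.2)
})

test_that("every saved draw respects orderings, truncations and u constraints", {
  cf <- simulation_config(J = 6, L = 2, M = 1, T = 8, studies_per_country = 2,
                          mid_ages = c(30, 50), seed = 3)
  w <- generate_world(cf)
  obs <- simulate_observations(w)
  fr <- model_frame(obs, w$hierarchy, cf$T, "adult")
  cfg <- sampler_config(n_chains = 1, iters = 150, burnin = 150, thin_to = 50,
                        seed = 5)
  ch <- run_chain(fr, cfg, chain_id = 1)
  lam <- exp(ch$hyper[, paste0("log_lambda_", c("c", "r", "s", "g"))])
  expect_true(all(lam[, 1] < lam[, 2] & lam[, 2] < lam[, 3] & lam[, 3] < lam[, 4]))
  expect_true(all(log(lam) <= 20))
  vv <- exp(ch$hyper[, paste0("log_v_", c("n", "s", "c"))])
  expect_true(all(vv[, 1] < vv[, 2] & vv[, 2] < vv[, 3]))
  # composite u per country has zero mean and zero fitted slope on every draw
  tc <- 1:cf$T - (cf$T + 1) / 2
  for (k in c(1, nrow(ch$u))) {
    for (j in seq_len(cf$J)) {
      u <- ch$u[k, (j - 1) * cf$T + 1:cf$T]
      expect_lt(abs(mean(u)), 1e-6)
      expect_lt(abs(sum(tc * u) / sum(tc^2)), 1e-6)
    }
  }
  expect_equal(length(ch$lp), 150)
  expect_true(all(is.finite(ch$lp)))
})

test_that("countries without data keep constrained prior draws for u", {
  cf <- simulation_config(J = 6, L = 2, M = 1, T = 8, studies_per_country = 2,
                          mid_ages = c(30, 50), seed = 3)
  w <- generate_world(cf)
  obs <- simulate_observations(w)
  obs <- obs[obs$country != 4, ]
  fr <- model_frame(obs, w$hierarchy, cf$T, "adult")
  st <- bmitrend:::dispersed_init(fr)
  set.seed(8)
  tc <- 1:cf$T - (cf$T + 1) / 2
  for (i in 1:5) {
    st <- gibbs_sweep(st, fr, list(adapt = TRUE))
    st <- mh_variance_step(st, fr, list(adapt = TRUE))
    expect_lt(abs(mean(st$uc[4, ])), 1e-8)
    expect_lt(abs(sum(tc * st$uc[4, ]) / sum(tc^2)), 1e-8)
  }
})

test_that("chains are deterministic and restart bit-for-bit from checkpoints", {
  cf <- simulation_config(J = 4, L = 2, M = 1, T = 6, studies_per_country = 2,
                          mid_ages = c(30, 50), seed = 6)
  w <- generate_world(cf)
  obs <- simulate_observations(w)
  fr <- model_frame(obs, w$hierarchy, cf$T, "adult")
  cfg <- sampler_config(n_chains = 1, iters = 40, burnin = 20, thin_to = 10, seed = 9)
  ch1 <- run_chain(fr, cfg, chain_id = 1)
  ch2 <- run_chain(fr, cfg, chain_id = 1)
  expect_identical(ch1$hyper, ch2$hyper)
  # checkpoint at iteration 30, then resume to the end
  ckdir <- tempfile()
  cfg_ck <- cfg; cfg_ck$checkpoint_every <- 30; cfg_ck$checkpoint_dir <- ckdir
  cfg_short <- cfg_ck; cfg_short$iters <- 10   # stop right at iteration 30
  invisible(run_chain(fr, cfg_short, chain_id = 1))
  ch3 <- run_chain(fr, cfg_ck, chain_id = 1,
                   resume_from = file.path(ckdir, "chain1.rds"))
  expect_identical(ch3$hyper, ch1$hyper)
  expect_identical(ch3$u, ch1$u)
})

test_that("pilot initialization inflates the fitted covariance by 1.5", {
  cf <- simulation_config(J = 4, L = 2, M = 1, T = 6, studies_per_country = 2,
                          mid_ages = c(30, 50), seed = 6)
  w <- generate_world(cf)
  obs <- simulate_observations(w)
  fr <- model_frame(obs, w$hierarchy, cf$T, "adult")
  cfg <- sampler_config(n_chains = 3, n_pilot_chains = 2, pilot_iters = 80,
                        pilot_burnin = 80, iters = 10, burnin = 10,
                        thin_to = 5, seed = 2)
  init <- initialize_from_pilot(fr, cfg)
  H <- do.call(rbind, lapply(init$pilot, `[[`, "hyper"))
  expect_equal(init$fit$cov, cov(H) * 1.5 + diag(1e-10, ncol(H)),
               tolerance = 1e-12)
  # generated start vectors reproduce the inflated covariance
  X <- sample_start_vectors(init$fit, 2e4)
  expect_equal(unname(diag(cov(X))), unname(diag(init$fit$cov)),
               tolerance = 0.06 * max(diag(init$fit$cov)) + 0.05)
  # all starting states satisfy the support constraints
  for (s in init$states) expect_true(state_in_support(s))
  init2 <- initialize_from_pilot(fr, cfg)
  expect_identical(hyper_vector_list(init$states), hyper_vector_list(init2$states))
})

hyper_vector_list <- function(states) lapply(states, function(s)
  c(s$ag, s$bg, log(s$tau2), log(s$lambda), log(s$v)))

test_that("stationary distribution passes simulation-based calibration", {
  # tiny reduction: one country, four national studies, only the study
  # effects and the latent prevalences are sampled; ranks of the true e_1
  # among its posterior draws must be uniform
  T <- 4
  h <- hierarchy_spec(region_of = 1L, sregion_of = 1L)
  obs0 <- data.frame(study_id = sprintf("s%d", rep(1:4, each = 2)),
                     country = 1L, year = rep(c(1, 2, 3, 4), each = 2),
                     sex = "female", mid_age = rep(c(30, 50), 4),
                     category = "obesity", y = 0, n = 300,
                     coverage = "national", urban_scope = "both",
                     country_urbanization = 0.5)
  v_true <- 0.04; tau2_true <- 0.01; a0 <- -1
  # 49 thinned draws give 50 equiprobable rank values, split into 10 bins
  n_rep <- 150; n_iter <- 256; burn <- 60; thin <- 4
  ranks <- integer(n_rep)
  set.seed(77)
  for (r in seq_len(n_rep)) {
    e_true <- rnorm(4, 0, sqrt(v_true))
    alpha_true <- rnorm(8, a0 + e_true[rep(1:4, each = 2)], sqrt(tau2_true))
    obs <- obs0
    obs$y <- rbinom(8, obs$n, pnorm(alpha_true))
    fr <- model_frame(obs, h, T, "adult")
    st <- new_model_state(fr)
    st$ag <- a0; st$tau2 <- tau2_true
    st$v <- c(n = v_true, s = 2 * v_true, c = 4 * v_true)
    st$alpha <- rnorm(8, a0, 0.1)
    ctrl <- list(blocks = c("alpha", "e"))
    draws <- numeric((n_iter - burn) %/% thin)
    for (it in seq_len(n_iter)) {
      ctrl$adapt <- it <= burn
      st <- gibbs_sweep(st, fr, ctrl)
      if (it > burn && (it - burn) %% thin == 0)
        draws[(it - burn) %/% thin] <- st$e[1]
    }
    ranks[r] <- sum(draws < e_true[1])
  }
  n_bins <- 10
  L <- (n_iter - burn) %/% thin
  bins <- cut(ranks, breaks = seq(-0.5, L + 0.5, length.out = n_bins + 1))
  obs_cnt <- as.vector(table(bins))
  chisq <- sum((obs_cnt - n_rep / n_bins)^2 / (n_rep / n_bins))
  expect_lt(chisq, qchisq(0.99, df = n_bins - 1))
})

test_that("metropolis acceptance rates are tracked and finite", {
  fr <- toy_frame()
  st <- randomize_state(fr, seed = 2)
  set.seed(4)
  for (i in 1:50) {
    st <- gibbs_sweep(st, fr, list(adapt = TRUE))
    st <- mh_variance_step(st, fr, list(adapt = TRUE))
  }
  acc <- st$.tune
  expect_true(is.finite(acc$acc_alpha / acc$n_alpha))
  expect_true(all(is.finite(acc$acc_lambda / acc$n_lambda)))
  expect_true(all(acc$acc_v <= acc$n_v))
  expect_true(state_in_support(st))
})
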