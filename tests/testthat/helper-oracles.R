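# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: matrix products are formed directly, densities
# are summed term by term with loops.

# second-difference penalty by direct construction with base::diff
oracle_penalty <- function(T) {
  D2 <- diff(diag(T), differences = 2)
  t(D2) %*% D2
}

# term-by-term log posterior for a model state (loops, no vectorized
# composition); mirrors the model: binomial + Gaussian alpha layer +
# hierarchical Gaussians + constrained RW2 + study effects + flat-on-SD
# hyperpriors
oracle_log_posterior <- function(state, frame) {
  h <- frame$hierarchy
  lp <- 0
  for (i in seq_len(frame$R)) {
    p <- pnorm(state$alpha[i])
    p <- min(max(p, 1e-15), 1 - 1e-15)
    lp <- lp + lchoose(frame$n[i], frame$y[i]) +
      frame$y[i] * log(p) + (frame$n[i] - frame$y[i]) * log(1 - p)
    j <- frame$country[i]
    l <- h$region_of[j]; m <- h$sregion_of_country[j]
    a_j <- state$ac[j] + state$ar[l] + state$as_[m] + state$ag
    b_j <- state$bc[j] + state$br[l] + state$bs[m] + state$bg
    u_jt <- state$uc[j, frame$year[i]] + state$ur[l, frame$year[i]] +
      state$us[m, frame$year[i]] + state$ug[frame$year[i]]
    gam <- 0
    for (k in 1:5) {
      psi <- state$psi_g[k] + state$psi_c[k, j] + state$psi_r[k, l] + state$psi_s[k, m]
      gam <- gam + psi * frame$B[i, k]
      if (!is.null(state$phi_g)) {
        phi <- state$phi_g[k] + state$phi_c[k, j] + state$phi_r[k, l] + state$phi_s[k, m]
        gam <- gam + phi * frame$B[i, k] * frame$tc[i]
      }
    }
    mu_i <- a_j + b_j * frame$tc[i] + u_jt + gam +
      sum(frame$X[i, ] * state$beta) + state$e[frame$study[i]]
    lp <- lp + dnorm(state$alpha[i], mu_i, sqrt(state$tau2), log = TRUE)
  }
  for (j in seq_len(frame$J)) lp <- lp +
    dnorm(state$ac[j], 0, sqrt(state$kappa["ac"]), log = TRUE) +
    dnorm(state$bc[j], 0, sqrt(state$kappa["bc"]), log = TRUE)
  for (l in seq_len(frame$L)) lp <- lp +
    dnorm(state$ar[l], 0, sqrt(state$kappa["ar"]), log = TRUE) +
    dnorm(state$br[l], 0, sqrt(state$kappa["br"]), log = TRUE)
  for (m in seq_len(frame$M)) lp <- lp +
    dnorm(state$as_[m], 0, sqrt(state$kappa["as_"]), log = TRUE) +
    dnorm(state$bs[m], 0, sqrt(state$kappa["bs"]), log = TRUE)
  P <- oracle_penalty(frame$T)
  Tm2 <- (frame$T - 2) / 2
  rw2 <- function(u, lam) Tm2 * log(lam) - lam / 2 * drop(t(u) %*% P %*% u)
  for (j in seq_len(frame$J)) lp <- lp + rw2(state$uc[j, ], state$lambda["c"])
  for (l in seq_len(frame$L)) lp <- lp + rw2(state$ur[l, ], state$lambda["r"])
  for (m in seq_len(frame$M)) lp <- lp + rw2(state$us[m, ], state$lambda["s"])
  lp <- lp + rw2(state$ug, state$lambda["g"])
  for (k in 1:5) {
    for (j in seq_len(frame$J)) lp <- lp +
      dnorm(state$psi_c[k, j], 0, sqrt(state$sigma2_psi[k, "c"]), log = TRUE)
    for (l in seq_len(frame$L)) lp <- lp +
      dnorm(state$psi_r[k, l], 0, sqrt(state$sigma2_psi[k, "r"]), log = TRUE)
    for (m in seq_len(frame$M)) lp <- lp +
      dnorm(state$psi_s[k, m], 0, sqrt(state$sigma2_psi[k, "s"]), log = TRUE)
    if (!is.null(state$phi_g)) {
      for (j in seq_len(frame$J)) lp <- lp +
        dnorm(state$phi_c[k, j], 0, sqrt(state$sigma2_phi[k, "c"]), log = TRUE)
      for (l in seq_len(frame$L)) lp <- lp +
        dnorm(state$phi_r[k, l], 0, sqrt(state$sigma2_phi[k, "r"]), log = TRUE)
      for (m in seq_len(frame$M)) lp <- lp +
        dnorm(state$phi_s[k, m], 0, sqrt(state$sigma2_phi[k, "s"]), log = TRUE)
    }
  }
  for (i in seq_len(frame$n_study)) lp <- lp +
    dnorm(state$e[i], 0, sqrt(state$v[frame$study_coverage[i]]), log = TRUE)
  lp <- lp - 0.5 * (sum(log(state$kappa)) + sum(log(state$sigma2_psi)) +
                      sum(log(state$v)) + log(state$tau2))
  if (!is.null(state$sigma2_phi)) lp <- lp - 0.5 * sum(log(state$sigma2_phi))
  lp <- lp - 1.5 * sum(log(state$lambda))
  unname(lp)
}

# small observation table for model-core tests: 2 countries (one region, one
# super-region), 2 studies each at different years
toy_obs <- function(T = 4, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(study = 1:4, age = c(30, 50))
  country <- c(1, 1, 2, 2)[grid$study]
  year <- c(1, 3, 2, 4)[grid$study]
  n <- 200
  data.frame(study_id = paste0("s", grid$study),
             country = country, year = year, sex = "female",
             mid_age = grid$age, category = "obesity",
             y = rbinom(nrow(grid), n, 0.15), n = n,
             coverage = rep(c("national", "subnational"), 4)[grid$study],
             urban_scope = "both",
             country_urbanization = 0.5)
}

toy_frame <- function(T = 4, seed = 1) {
  h <- hierarchy_spec(region_of = c(1, 1), sregion_of = 1)
  model_frame(toy_obs(T, seed), h, T, "adult")
}

# fill a state with small random values in support
randomize_state <- function(frame, seed = 1) {
  set.seed(seed)
  st <- new_model_state(frame)
  st$ag <- rnorm(1, -1, 0.1); st$bg <- rnorm(1, 0, 0.01)
  st$ac <- rnorm(frame$J, 0, 0.1); st$ar <- rnorm(frame$L, 0, 0.1)
  st$as_ <- rnorm(frame$M, 0, 0.1)
  st$bc <- rnorm(frame$J, 0, 0.01); st$br <- rnorm(frame$L, 0, 0.01)
  st$bs <- rnorm(frame$M, 0, 0.01)
  pe <- bmitrend:::rw2_penalty_eigen(frame$T)
  st$uc <- t(sapply(seq_len(frame$J), function(j) bmitrend:::rconstrained_rw2(pe, 3000)))
  st$ur <- t(sapply(seq_len(frame$L), function(l) bmitrend:::rconstrained_rw2(pe, 6000)))
  st$us <- matrix(bmitrend:::rconstrained_rw2(pe, 9000), frame$M, frame$T, byrow = TRUE)
  st$ug <- bmitrend:::rconstrained_rw2(pe, 12000)
  st$psi_g <- rnorm(5, 0, 0.001)
  st$psi_c <- matrix(rnorm(5 * frame$J, 0, 1e-3), 5)
  st$psi_r <- matrix(rnorm(5 * frame$L, 0, 1e-3), 5)
  st$psi_s <- matrix(rnorm(5 * frame$M, 0, 1e-3), 5)
  if (!is.null(st$phi_g)) {
    st$phi_g <- rnorm(5, 0, 1e-4)
    st$phi_c <- matrix(rnorm(5 * frame$J, 0, 1e-4), 5)
    st$phi_r <- matrix(rnorm(5 * frame$L, 0, 1e-4), 5)
    st$phi_s <- matrix(rnorm(5 * frame$M, 0, 1e-4), 5)
  }
  st$beta <- rnorm(8, 0, 0.02)
  st$e <- rnorm(frame$n_study, 0, 0.05)
  st$alpha <- rnorm(frame$R, latent_mean(st, frame), sqrt(st$tau2))
  st
}

# conjugate single-level reduction: one country, S national studies, alpha
# treated as observed data, variances fixed. The remaining unknowns
# (composite intercept a*, slope b*, study effects e) are jointly Gaussian
# with a posterior available in closed form.
conjugate_toy <- function(S = 4, rows_per = 2, T = 6, tau2 = 0.01, v = 0.04,
                          seed = 2) {
  set.seed(seed)
  years <- rep(seq(1, T, length.out = S), each = rows_per)
  obs <- data.frame(study_id = rep(sprintf("s%d", 1:S), each = rows_per),
                    country = 1L, year = round(years), sex = "female",
                    mid_age = rep_len(c(30, 50, 40), S * rows_per),
                    category = "obesity",
                    y = 50, n = 400,
                    coverage = "national", urban_scope = "both",
                    country_urbanization = 0.5)
  h <- hierarchy_spec(region_of = 1L, sregion_of = 1L)
  frame <- model_frame(obs, h, T, "adult")
  a_true <- -1; b_true <- 0.02
  e_true <- rnorm(S, 0, sqrt(v))
  alpha <- rnorm(frame$R, a_true + b_true * frame$tc + e_true[frame$study],
                 sqrt(tau2))
  list(frame = frame, alpha = alpha, tau2 = tau2, v = v, S = S)
}

# closed-form posterior for the conjugate toy: theta = (a*, b*, e_1..e_S),
# flat prior on (a*, b*), e ~ N(0, v); alpha = Z theta + N(0, tau2)
conjugate_posterior <- function(toy) {
  fr <- toy$frame
  Z <- cbind(1, fr$tc,
             sapply(seq_len(toy$S), function(s) as.numeric(fr$study == s)))
  prior_prec <- diag(c(0, 0, rep(1 / toy$v, toy$S)))
  Q <- crossprod(Z) / toy$tau2 + prior_prec
  b <- crossprod(Z, toy$alpha) / toy$tau2
  Sigma <- solve(Q)
  list(mean = as.vector(Sigma %*% b), cov = Sigma, Z = Z)
}

# batch-means Monte Carlo standard error
bm_se <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), 0.0)
  sd(means) / sqrt(n_batch)
}
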