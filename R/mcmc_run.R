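#' Sampler configuration
#'
#' @param n_chains number of final chains.
#' @param iters post-burn-in iterations per final chain.
#' @param burnin burn-in iterations discarded from each final chain (proposal
#'   scales adapt during burn-in only).
#' @param thin_to total combined posterior draw count after thinning.
#' @param n_pilot_chains,pilot_iters,pilot_burnin the initial pilot phase used
#'   to build overdispersed starting values.
#' @param inflation factor multiplying the pilot posterior covariance when
#'   fitting the multivariate Gaussian that generates final-chain starts
#'   (1.5 gives roughly 50% overdispersion relative to the target posterior).
#' @param seed master seed; each pilot and final chain gets its own stream
#'   derived from it.
#' @param pilot logical: run the pilot initialization phase before the final
#'   chains (dispersed defaults otherwise).
#' @param blocks optional subset of sweep blocks to update (see
#'   [gibbs_sweep()]); all by default.
#' @param fix_alpha treat the latent alpha as fixed data (used for conjugate
#'   reductions).
#' @param checkpoint_every,checkpoint_dir optional checkpointing of chain
#'   state every so many iterations.
#' @return an object of class "sampler_config".
#' @export
sampler_config <- function(n_chains = 4, iters = 2500, burnin = 2500,
                           thin_to = 500,
                           n_pilot_chains = 2, pilot_iters = 300,
                           pilot_burnin = 300, inflation = 1.5, pilot = TRUE,
                           seed = 1L, blocks = NULL, fix_alpha = FALSE,
                           checkpoint_every = NULL, checkpoint_dir = NULL) {
  stopifnot(n_chains >= 1, iters >= 1, burnin >= 0, thin_to >= 1,
            inflation > 1)
  structure(as.list(environment()), class = "sampler_config")
}

# deterministic derived seed, kept below 2^31 - 1
derive_seed <- function(master, i) {
  ((as.double(master) %% 100000) * 131071 + as.double(i) * 524287) %% 2147483647
}

# names of the non-study-specific ("hyper") parameter vector used for pilot
# initialization and diagnostics
hyper_names <- function(population) {
  nm <- c(paste0("log_kappa_", c("ac", "ar", "as", "bc", "br", "bs")),
          paste0("log_lambda_", c("c", "r", "s", "g")),
          paste0("log_v_", c("n", "s", "c")), "log_tau2",
          "ag", "bg", paste0("psi_g", 1:5))
  if (population == "adult") nm <- c(nm, paste0("phi_g", 1:5))
  nm
}

hyper_vector <- function(state) {
  x <- c(log(state$kappa), log(state$lambda), log(state$v), log(state$tau2),
         state$ag, state$bg, state$psi_g)
  if (!is.null(state$phi_g)) x <- c(x, state$phi_g)
  names(x) <- hyper_names(state$population)
  x
}

set_hyper_vector <- function(state, x) {
  state$kappa[] <- exp(x[1:6])
  state$lambda[] <- exp(x[7:10])
  state$v[] <- exp(x[11:13])
  state$tau2 <- exp(x[14])
  state$ag <- x[15]; state$bg <- x[16]
  state$psi_g <- unname(x[17:21])
  if (!is.null(state$phi_g)) state$phi_g <- unname(x[22:26])
  state
}

# conditional generation of all remaining parameters given the hyper vector:
# hierarchical components from their priors, u from the constrained RW2
# prior, study effects from their coverage-dependent Gaussians, then alpha
# around its latent mean
conditional_init <- function(frame, state) {
  J <- frame$J; L <- frame$L; M <- frame$M
  state$ac <- stats::rnorm(J, 0, sqrt(state$kappa["ac"]))
  state$ar <- stats::rnorm(L, 0, sqrt(state$kappa["ar"]))
  state$as_ <- stats::rnorm(M, 0, sqrt(state$kappa["as_"]))
  state$bc <- stats::rnorm(J, 0, sqrt(state$kappa["bc"]))
  state$br <- stats::rnorm(L, 0, sqrt(state$kappa["br"]))
  state$bs <- stats::rnorm(M, 0, sqrt(state$kappa["bs"]))
  state$uc <- t(replicate(J, rconstrained_rw2(frame$P_eigen, state$lambda["c"])))
  state$ur <- t(replicate(L, rconstrained_rw2(frame$P_eigen, state$lambda["r"])))
  state$us <- t(replicate(M, rconstrained_rw2(frame$P_eigen, state$lambda["s"])))
  state$ug <- rconstrained_rw2(frame$P_eigen, state$lambda["g"])
  for (k in 1:5) {
    state$psi_c[k, ] <- stats::rnorm(J, 0, sqrt(state$sigma2_psi[k, "c"]))
    state$psi_r[k, ] <- stats::rnorm(L, 0, sqrt(state$sigma2_psi[k, "r"]))
    state$psi_s[k, ] <- stats::rnorm(M, 0, sqrt(state$sigma2_psi[k, "s"]))
    if (!is.null(state$phi_g)) {
      state$phi_c[k, ] <- stats::rnorm(J, 0, sqrt(state$sigma2_phi[k, "c"]))
      state$phi_r[k, ] <- stats::rnorm(L, 0, sqrt(state$sigma2_phi[k, "r"]))
      state$phi_s[k, ] <- stats::rnorm(M, 0, sqrt(state$sigma2_phi[k, "s"]))
    }
  }
  state$e <- stats::rnorm(frame$n_study, 0,
                          sqrt(state$v[frame$study_coverage]))
  state$alpha <- stats::rnorm(frame$R, latent_mean(state, frame), sqrt(state$tau2))
  state
}

# dispersed starting state for pilot chains: log variances drawn from diffuse
# Gaussians centred on scale-aware defaults (orderings enforced by sorting),
# the global intercept, slope and spline coefficients centred on a crude
# probit-scale regression of the empirical prevalences, country intercepts on
# shrunken country residual means, and everything else generated
# conditionally. Starting near the data keeps the early residual sum of
# squares on the right scale, so the residual variance does not open wide
# and decouple the latent prevalences from the mean structure.
dispersed_init <- function(frame) {
  state <- new_model_state(frame)
  hx <- hyper_vector(state)
  nlv <- 14L  # count of log-variance entries
  hx[1:nlv] <- hx[1:nlv] + stats::rnorm(nlv, 0, 0.7)
  hx[7:10] <- sort(hx[7:10])   # lambda ordering
  hx[11:13] <- sort(hx[11:13]) # v ordering
  state <- clamp_to_support(set_hyper_vector(state, hx))
  state <- conditional_init(frame, state)

  emp <- stats::qnorm(pmin(pmax((frame$y + 0.5) / (frame$n + 1), 1e-6), 1 - 1e-6))
  X0 <- cbind(1, frame$tc, frame$B)
  cf <- stats::lm.fit(X0, emp)$coefficients
  cf[is.na(cf)] <- 0
  state$ag <- cf[1] + stats::rnorm(1, 0, 0.1)
  state$bg <- cf[2] + stats::rnorm(1, 0, 0.005)
  state$psi_g <- unname(cf[3:7])
  resid <- emp - as.vector(X0 %*% cf)
  cmean <- vapply(frame$rows_by_country, function(r)
    if (length(r)) mean(resid[r]) else 0, 0.0)
  state$ac <- 0.8 * cmean
  state$alpha <- stats::rnorm(frame$R, latent_mean(state, frame), sqrt(state$tau2))
  state
}

#' Run one MCMC chain
#'
#' Alternates [gibbs_sweep()] and [mh_variance_step()], discards the burn-in,
#' and stores per-iteration parameter blocks needed for country-year-age
#' inference (composite a, b, u, psi, phi per country), the hyperparameter
#' vector, and the log-posterior trace. Proposal scales adapt during burn-in
#' and are frozen afterwards. Aborts with the iteration index if the
#' log-posterior becomes non-finite.
#'
#' @param frame a [model_frame()].
#' @param config a [sampler_config()].
#' @param chain_id integer chain id (determines the chain's seed stream).
#' @param init_state optional starting state; a dispersed default otherwise.
#' @param resume_from optional checkpoint file written by a previous call.
#' @return a list of class "chain_draws": matrices a, b (draws x J),
#'   u (draws x J*T, column (j-1)*T + t), psi, phi (draws x 5J), hyper, lp,
#'   plus acceptance summaries.
#' @export
run_chain <- function(frame, config, chain_id = 1L, init_state = NULL,
                      resume_from = NULL) {
  n_iter <- config$burnin + config$iters
  J <- frame$J; T <- frame$T
  npred <- c(a = J, b = J, u = J * T, psi = 5 * J,
             phi = if (frame$population == "adult") 5 * J else 0)
  if (!is.null(resume_from)) {
    ck <- readRDS(resume_from)
    state <- ck$state; start_iter <- ck$iter + 1L
    store <- ck$store
    # the resumed run may be configured longer than the checkpointed one
    grow <- function(m) {
      if (is.null(m)) return(NULL)
      if (is.matrix(m) && nrow(m) < config$iters)
        rbind(m, matrix(NA_real_, config$iters - nrow(m), ncol(m),
                        dimnames = list(NULL, colnames(m))))
      else if (!is.matrix(m) && length(m) < config$iters)
        c(m, rep(NA_real_, config$iters - length(m)))
      else m
    }
    store <- lapply(store, grow)
    assign(".Random.seed", ck$random_seed, envir = globalenv())
  } else {
    set.seed(derive_seed(config$seed, chain_id))
    state <- if (is.null(init_state)) dispersed_init(frame) else init_state
    start_iter <- 1L
    store <- list(
      a = matrix(NA_real_, config$iters, J),
      b = matrix(NA_real_, config$iters, J),
      u = matrix(NA_real_, config$iters, J * T),
      psi = matrix(NA_real_, config$iters, 5 * J),
      phi = if (npred["phi"] > 0) matrix(NA_real_, config$iters, 5 * J) else NULL,
      hyper = matrix(NA_real_, config$iters, length(hyper_names(frame$population)),
                     dimnames = list(NULL, hyper_names(frame$population))),
      lp = rep(NA_real_, config$iters))
  }
  h <- frame$hierarchy
  ctrl_adapt <- list(blocks = config$blocks, adapt = TRUE, fix_alpha = config$fix_alpha)
  ctrl_frozen <- list(blocks = config$blocks, adapt = FALSE, fix_alpha = config$fix_alpha)
  # variances are held at their starting values for the first quarter of
  # burn-in so the mean structure locks onto the data first
  freeze_until <- if (is.null(config$blocks)) config$burnin %/% 4L else 0L
  for (it in start_iter:n_iter) {
    ctrl <- if (it <= config$burnin) ctrl_adapt else ctrl_frozen
    if (it <= freeze_until) {
      ctrl$blocks <- setdiff(ctrl$blocks %||%
                               c("alpha", "e", "beta", "linear", "u", "spline", "variances"),
                             "variances")
    }
    state <- gibbs_sweep(state, frame, ctrl)
    if ((is.null(config$blocks) || "variances" %in% config$blocks) && it > freeze_until)
      state <- mh_variance_step(state, frame, ctrl)
    if (it > config$burnin) {
      k <- it - config$burnin
      store$a[k, ] <- composite_a(state, h)
      store$b[k, ] <- composite_b(state, h)
      store$u[k, ] <- as.vector(t(composite_u(state, h)))  # (j-1)*T + t
      store$psi[k, ] <- as.vector(composite_psi(state, h)) # 5 x J column-major
      if (!is.null(store$phi)) store$phi[k, ] <- as.vector(composite_phi(state, h))
      store$hyper[k, ] <- hyper_vector(state)
      store$lp[k] <- log_posterior(state, frame)
      if (!is.finite(store$lp[k]))
        stop(sprintf("non-finite log-posterior at iteration %d of chain %d", it, chain_id))
    }
    if (!is.null(config$checkpoint_every) && it %% config$checkpoint_every == 0) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(state = state, iter = it, store = store,
                   random_seed = get(".Random.seed", envir = globalenv())),
              file.path(config$checkpoint_dir, sprintf("chain%d.rds", chain_id)))
    }
  }
  structure(list(a = store$a, b = store$b, u = store$u, psi = store$psi,
                 phi = store$phi, hyper = store$hyper, lp = store$lp,
                 chain_id = chain_id,
                 acceptance = list(
                   alpha = state$.tune$acc_alpha / max(state$.tune$n_alpha, 1),
                   lambda = state$.tune$acc_lambda / pmax(state$.tune$n_lambda, 1),
                   v = state$.tune$acc_v / pmax(state$.tune$n_v, 1)),
                 final_state = state),
            class = "chain_draws")
}

#' Starting states from a pilot phase
#'
#' Runs a set of short pilot chains from dispersed starting values, fits a
#' multivariate Gaussian to the pooled posterior draws of the non-study-
#' specific parameters, scales its covariance by the configured inflation
#' factor (default 1.5, i.e. about 50% overdispersion relative to the target
#' posterior), and samples starting hyperparameter vectors from it, resampling
#' until the ordering and truncation constraints hold. Study random effects
#' and the latent alpha are then generated conditionally.
#'
#' @param frame a [model_frame()].
#' @param config a [sampler_config()].
#' @return list with `states` (length n_chains), `fit` (list mean, cov) and
#'   `pilot` (pilot chain draws).
#' @export
initialize_from_pilot <- function(frame, config) {
  pilot_cfg <- config
  pilot_cfg$iters <- config$pilot_iters
  pilot_cfg$burnin <- config$pilot_burnin
  pilot_cfg$checkpoint_every <- NULL
  pilot <- lapply(seq_len(config$n_pilot_chains), function(i)
    run_chain(frame, pilot_cfg, chain_id = 1000L + i))
  H <- do.call(rbind, lapply(pilot, `[[`, "hyper"))
  if (!all(is.finite(H))) stop("pilot chains produced non-finite draws")
  mu <- colMeans(H)
  S <- stats::cov(H) * config$inflation
  S <- S + diag(1e-10, ncol(S))
  Rch <- chol(S)
  template <- new_model_state(frame)
  states <- vector("list", config$n_chains)
  set.seed(derive_seed(config$seed, 777L))
  for (i in seq_len(config$n_chains)) {
    tries <- 0L
    repeat {
      x <- mu + as.vector(stats::rnorm(length(mu)) %*% Rch)
      names(x) <- names(mu)
      cand <- set_hyper_vector(template, x)
      if (state_in_support(cand)) break
      tries <- tries + 1L
      if (tries >= 500L) { cand <- clamp_to_support(cand); break }
    }
    states[[i]] <- conditional_init(frame, cand)
  }
  list(states = states, fit = list(mean = mu, cov = S), pilot = pilot)
}

#' Sample starting hyperparameter vectors from a fitted pilot Gaussian
#'
#' Exposed separately so the overdispersion of generated starts can be
#' checked directly against the fitted covariance.
#'
#' @param fit list with `mean` and `cov` (already inflated).
#' @param n number of vectors.
#' @return matrix n x length(mean).
#' @export
sample_start_vectors <- function(fit, n) {
  Rch <- chol(fit$cov + diag(1e-12, length(fit$mean)))
  sweep(matrix(stats::rnorm(n * length(fit$mean)), n) %*% Rch, 2, fit$mean, `+`)
}

#' Fit the prevalence model
#'
#' End-to-end fit for one BMI category and sex: builds the model frame, runs
#' the pilot initialization phase, runs the final chains, and thins and
#' combines the post-burn-in draws.
#'
#' @param obs observation table (one category).
#' @param hierarchy a [hierarchy_spec()].
#' @param T number of years.
#' @param population "adult" or "child_adolescent".
#' @param config a [sampler_config()].
#' @param pilot logical; FALSE starts every chain from a dispersed default
#'   instead of the pilot-phase Gaussian (used for reductions and tests).
#' @return an object of class "bmi_fit": frame metadata, per-chain draws,
#'   combined thinned draws, acceptance rates.
#' @export
fit_prevalence_model <- function(obs, hierarchy, T,
                                 population = c("adult", "child_adolescent"),
                                 config = sampler_config(),
                                 pilot = config$pilot %||% TRUE) {
  population <- match.arg(population)
  frame <- model_frame(obs, hierarchy, T, population)
  starts <- if (pilot) initialize_from_pilot(frame, config)$states
            else vector("list", config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(i)
    run_chain(frame, config, chain_id = i, init_state = starts[[i]]))
  combined <- thin_and_combine(chains, config$thin_to)
  structure(list(J = frame$J, L = frame$L, M = frame$M, T = frame$T,
                 hierarchy = frame$hierarchy, population = frame$population,
                 knots = frame$knots, age_center = frame$age_center,
                 t_center = frame$t_center,
                 chains = chains, combined = combined, config = config,
                 acceptance = lapply(chains, `[[`, "acceptance")),
            class = "bmi_fit")
}

#' Thin and combine chains
#'
#' Evenly spaced within-chain thinning followed by concatenation; the output
#' draw count equals `target` exactly and per-chain contributions differ by
#' at most one.
#'
#' @param chains list of chain_draws.
#' @param target combined draw count.
#' @return a list with the same matrices as a chain, plus `chain` (origin id).
#' @export
thin_and_combine <- function(chains, target) {
  m <- length(chains)
  n <- nrow(chains[[1]]$hyper)
  total <- n * m
  if (total < target)
    stop(sprintf("insufficient draws: have %d post-burn-in, need %d", total, target))
  base <- target %/% m
  cnts <- rep(base, m) + c(rep(1, target %% m), rep(0, m - target %% m))
  pick <- function(cnt) if (cnt == 0) integer(0) else ceiling(seq_len(cnt) * n / cnt)
  fields <- c("a", "b", "u", "psi", "phi", "hyper")
  out <- list()
  for (f in fields) {
    if (is.null(chains[[1]][[f]])) { out[f] <- list(NULL); next }
    out[[f]] <- do.call(rbind, lapply(seq_len(m), function(i)
      chains[[i]][[f]][pick(cnts[i]), , drop = FALSE]))
  }
  out$lp <- unlist(lapply(seq_len(m), function(i) chains[[i]]$lp[pick(cnts[i])]))
  out$chain <- rep(seq_len(m), cnts)
  out
}

#' Split-Rhat convergence diagnostic
#'
#' Standard split-Rhat: each chain is halved, and the ratio of pooled to
#' within-half variance is computed over the resulting half-chains. Values
#' near 1 indicate convergence. Chains with zero variance return the sentinel
#' value 1 with attribute `degenerate = TRUE` (a constant chain is trivially
#' converged) rather than propagating NaN.
#'
#' @param draws matrix (iterations x chains) or list of equal-length numeric
#'   vectors, one per chain.
#' @return numeric split-Rhat value.
#' @export
split_rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  if (!is.matrix(draws)) stop("draws must be a matrix or list of chains")
  if (ncol(draws) < 2) stop("split-Rhat needs at least 2 chains")
  n <- nrow(draws)
  if (n < 4) stop("split-Rhat needs at least 4 draws per chain")
  half <- n %/% 2
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[half + seq_len(half), j])))
  m <- ncol(halves); nn <- nrow(halves)
  W <- mean(apply(halves, 2, stats::var))
  B <- nn * stats::var(colMeans(halves))
  if (!is.finite(W) || W <= 0) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
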