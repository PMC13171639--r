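# Full-conditional and Metropolis updates for the Metropolis-within-Gibbs
# sampler. Update order within a sweep is fixed: alpha, e, beta, linear a/b
# components, u components by level (country, region, super-region, global),
# spline coefficients, then variances. Proposal scales for the Metropolis
# steps adapt toward 0.44 acceptance during burn-in only and are frozen
# afterwards, preserving the stationary distribution.

VARIANCE_FLOOR <- 1e-12

new_tuning <- function(frame) {
  # alpha proposal scale seeded from the binomial information at p ~ 0.5
  list(ls_alpha = log(2.4) - 0.5 * log(pmax(frame$n, 5)),
       ls_lambda = rep(-1.0, 4),
       ls_v = rep(-0.7, 3),
       ls_sig_psi = rep(-0.7, 5), ls_sig_phi = rep(-0.7, 5),
       ls_kappa_c = rep(-0.7, 2), ls_tau = -0.7,
       acc_alpha = 0, acc_lambda = numeric(4), acc_v = numeric(3),
       acc_sig = numeric(10), acc_kappa_c = numeric(2), acc_tau = 0,
       n_alpha = 0, n_lambda = numeric(4), n_v = numeric(3),
       n_sig = numeric(10), n_kappa_c = numeric(2), n_tau = 0)
}

# binomial log likelihood, continuous in n (effective sample sizes are real);
# equals dbinom(..., log = TRUE) exactly at integer n
binom_loglik <- function(y, n, alpha) {
  p <- stats::pnorm(alpha)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  lchoose(n, y) + y * log(p) + (n - y) * log1p(-p)
}

# per-row mean components of the latent Gaussian layer
row_components <- function(state, frame) {
  h <- frame$hierarchy
  cn <- frame$country
  a_comp <- composite_a(state, h); b_comp <- composite_b(state, h)
  m_ab <- a_comp[cn] + b_comp[cn] * frame$tc
  U <- composite_u(state, h)
  m_u <- U[cbind(cn, frame$year)]
  psi <- composite_psi(state, h); phi <- composite_phi(state, h)
  m_age <- rowSums(frame$B * t(psi)[cn, , drop = FALSE])
  if (!is.null(phi)) m_age <- m_age + rowSums(frame$Bt * t(phi)[cn, , drop = FALSE])
  m_x <- as.vector(frame$X %*% state$beta)
  m_e <- state$e[frame$study]
  list(m_ab = m_ab, m_u = m_u, m_age = m_age, m_x = m_x, m_e = m_e,
       mu = m_ab + m_u + m_age + m_x + m_e)
}

# Exact constrained conditional draw of one RW2 vector, parameterized on the
# span of the penalty's non-null eigenvectors (zero mean and zero OLS slope by
# construction). This is algebraically identical to drawing from the
# unconstrained conditional and applying the Rue-Held correction for the mean
# and slope constraints, and it degrades gracefully: units with data at a
# single time point get a proper draw with the non-identified direction
# carried by the prior, and units with no data get a constrained prior draw.
draw_u_subspace <- function(frame, G, lam, ysum, tau2) {
  b <- as.vector(crossprod(frame$V, ysum)) / tau2
  M <- G / tau2
  diag(M) <- diag(M) + lam * frame$Dvals
  Rch <- chol(M)
  w <- backsolve(Rch, forwardsolve(t(Rch), b)) + backsolve(Rch, stats::rnorm(length(b)))
  as.vector(frame$V %*% w)
}

# log marginal likelihood of lambda for one unit, with the unit's u vector
# integrated out: (T-2)/2 log(lam) - log det(M)/2 + b' M^{-1} b / 2
lambda_unit_marginal <- function(frame, G, lam, b, tau2) {
  M <- G / tau2
  diag(M) <- diag(M) + lam * frame$Dvals
  Rch <- chol(M)
  z <- forwardsolve(t(Rch), b)
  (length(frame$Dvals) / 2) * log(lam) - sum(log(diag(Rch))) + sum(z^2) / 2
}

u_level_spec <- function(state, frame) {
  list(
    list(name = "uc", li = 1L, g = frame$country, rows = frame$rows_by_country,
         G = frame$agg$G_c),
    list(name = "ur", li = 2L, g = frame$region, rows = frame$rows_by_region,
         G = frame$agg$G_r),
    list(name = "us", li = 3L, g = frame$sregion, rows = frame$rows_by_sregion,
         G = frame$agg$G_s),
    list(name = "ug", li = 4L, g = rep(1L, frame$R), rows = list(seq_len(frame$R)),
         G = frame$agg$G_g))
}

# per-unit year-sum vector of a residual over the unit's rows
year_sums <- function(frame, rows, r) {
  ysum <- numeric(frame$T)
  if (length(rows)) {
    s <- rowsum(r[rows], frame$year[rows])
    ysum[as.integer(rownames(s))] <- s
  }
  ysum
}

#' One Gibbs sweep over the Gaussian blocks and the latent prevalences
#'
#' Updates, in fixed order: the latent probit prevalences alpha (adaptive
#' random-walk Metropolis against the binomial likelihood -- the one
#' non-Gaussian conditional), study random effects e, study-design offsets
#' beta, the hierarchical linear intercept/slope components, the RW2
#' components by level from their exact constrained full conditionals (the
#' subspace parameterization of the zero-mean zero-slope constraints,
#' equivalent to the Rue-Held correction, with no-data units falling back to
#' constrained prior draws), the spline coefficient components, and the
#' conjugate variance parameters (tau2, kappa's, sigma2's) from their exact
#' truncated inverse-gamma full conditionals. Ordered or truncated variance
#' parameters (lambda's, v's) are handled by [mh_variance_step()].
#'
#' @param state a [new_model_state()] in the prior support.
#' @param frame a [model_frame()].
#' @param ctrl list: `blocks` (character subset of "alpha", "e", "beta",
#'   "linear", "u", "spline", "variances"; default all), `adapt` (logical,
#'   adapt Metropolis scales), `fix_alpha` (treat alpha as fixed data).
#' @return the updated state (tuning state travels in `state$.tune`).
#' @export
gibbs_sweep <- function(state, frame, ctrl = list()) {
  blocks <- ctrl$blocks %||% c("alpha", "e", "beta", "linear", "u", "spline", "variances")
  adapt <- isTRUE(ctrl$adapt)
  if (is.null(state$.tune)) state$.tune <- new_tuning(frame)
  h <- frame$hierarchy
  cn <- frame$country; rg <- frame$region; sg <- frame$sregion
  yr <- frame$year; tc <- frame$tc; B <- frame$B; Bt <- frame$Bt
  tau2 <- state$tau2
  gain <- 0.05

  gsum <- function(x, g, nlev) {
    out <- numeric(nlev)
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s
    out
  }

  comp <- row_components(state, frame)
  m_ab <- comp$m_ab; m_u <- comp$m_u; m_age <- comp$m_age
  m_x <- comp$m_x; m_e <- comp$m_e; mu <- comp$mu

  ## --- alpha: random-walk Metropolis against binomial likelihood ----------
  if ("alpha" %in% blocks && !isTRUE(ctrl$fix_alpha)) {
    s_al <- exp(state$.tune$ls_alpha)
    prop <- state$alpha + s_al * stats::rnorm(frame$R)
    logr <- binom_loglik(frame$y, frame$n, prop) -
      binom_loglik(frame$y, frame$n, state$alpha) +
      stats::dnorm(prop, mu, sqrt(tau2), log = TRUE) -
      stats::dnorm(state$alpha, mu, sqrt(tau2), log = TRUE)
    acc <- log(stats::runif(frame$R)) < logr
    state$alpha[acc] <- prop[acc]
    state$.tune$acc_alpha <- state$.tune$acc_alpha + mean(acc)
    state$.tune$n_alpha <- state$.tune$n_alpha + 1
    if (adapt) state$.tune$ls_alpha <- state$.tune$ls_alpha + gain * (acc - 0.44)
  }
  alpha <- state$alpha

  ## --- study random effects e ---------------------------------------------
  if ("e" %in% blocks) {
    r <- alpha - (mu - m_e)
    sums <- gsum(r, frame$study, frame$n_study)
    prec <- frame$agg$cnt_study / tau2 + 1 / state$v[frame$study_coverage]
    state$e <- stats::rnorm(frame$n_study, (sums / tau2) / prec, sqrt(1 / prec))
    m_e <- state$e[frame$study]
    mu <- m_ab + m_u + m_age + m_x + m_e
  }

  ## --- beta (flat prior, identified columns only) --------------------------
  if ("beta" %in% blocks && length(frame$beta_idx)) {
    idx <- frame$beta_idx
    Xi <- frame$X[, idx, drop = FALSE]
    r <- alpha - (mu - m_x)
    Q <- crossprod(Xi) / tau2
    bv <- crossprod(Xi, r) / tau2
    bnew <- state$beta
    bnew[idx] <- joint_gaussian_draw(Q + diag(1e-10, length(idx)), bv)
    state$beta <- bnew
    m_x <- as.vector(frame$X %*% bnew)
    mu <- m_ab + m_u + m_age + m_x + m_e
  }

  ## --- hierarchical linear components --------------------------------------
  if ("linear" %in% blocks) {
    r0 <- alpha - (mu - m_ab)
    upd <- function(x, g, nlev, coefsq, coef, priorvar) {
      rr <- r0 - m_ab + coef * x[g]
      sums <- gsum(rr * coef, g, nlev)
      prec <- coefsq / tau2 + 1 / priorvar
      xn <- stats::rnorm(nlev, (sums / tau2) / prec, sqrt(1 / prec))
      m_ab <<- m_ab + coef * (xn - x)[g]
      xn
    }
    one <- rep(1, frame$R)
    state$ac <- upd(state$ac, cn, frame$J, frame$agg$cnt_c, one, state$kappa["ac"])
    state$ar <- upd(state$ar, rg, frame$L, frame$agg$cnt_r, one, state$kappa["ar"])
    state$as_ <- upd(state$as_, sg, frame$M, frame$agg$cnt_s, one, state$kappa["as_"])
    state$ag <- upd(state$ag, rep(1L, frame$R), 1L, frame$R, one, Inf)
    state$bc <- upd(state$bc, cn, frame$J, frame$agg$tc2_c, tc, state$kappa["bc"])
    state$br <- upd(state$br, rg, frame$L, frame$agg$tc2_r, tc, state$kappa["br"])
    state$bs <- upd(state$bs, sg, frame$M, frame$agg$tc2_s, tc, state$kappa["bs"])
    state$bg <- upd(state$bg, rep(1L, frame$R), 1L, frame$agg$tc2_g, tc, Inf)
    mu <- m_ab + m_u + m_age + m_x + m_e
  }

  ## --- RW2 components by level ---------------------------------------------
  if ("u" %in% blocks) {
    # r1 excludes the whole u contribution and stays fixed across levels;
    # m_u tracks the current total u contribution per row
    r1 <- alpha - (mu - m_u)
    for (lv in u_level_spec(state, frame)) {
      Umat <- if (lv$name == "ug") matrix(state$ug, 1, frame$T) else state[[lv$name]]
      m_u_level <- Umat[cbind(lv$g, yr)]
      rlev <- r1 - (m_u - m_u_level)
      lam <- state$lambda[lv$li]
      for (uidx in seq_len(nrow(Umat))) {
        rows <- lv$rows[[uidx]]
        un <- draw_u_subspace(frame, lv$G[[uidx]], lam,
                              year_sums(frame, rows, rlev), tau2)
        delta <- un - Umat[uidx, ]
        Umat[uidx, ] <- un
        if (length(rows)) m_u[rows] <- m_u[rows] + delta[yr[rows]]
      }
      if (lv$name == "ug") state$ug <- Umat[1, ] else state[[lv$name]] <- Umat
    }
    mu <- m_ab + m_u + m_age + m_x + m_e
  }

  ## --- spline coefficients --------------------------------------------------
  if ("spline" %in% blocks) {
    r2 <- alpha - (mu - m_age)
    # joint 5-vector draw per unit: exact full conditional with the prior
    # precision, avoiding the near-collinearity of the truncated-power basis
    # on coarse age grids
    upd_level <- function(mat, g, rows_list, D, DtD, sigma2) {
      contrib <- rowSums(D * t(mat)[g, , drop = FALSE])
      rloc <- r2 - m_age + contrib
      for (u in seq_len(ncol(mat))) {
        rows <- rows_list[[u]]
        if (!length(rows)) {
          xn <- stats::rnorm(5, 0, sqrt(sigma2))
        } else {
          Q <- DtD[[u]] / tau2 + diag(1 / sigma2)
          bv <- crossprod(D[rows, , drop = FALSE], rloc[rows]) / tau2
          xn <- joint_gaussian_draw(Q, bv)
        }
        delta <- xn - mat[, u]
        mat[, u] <- xn
        if (length(rows))
          m_age[rows] <<- m_age[rows] + as.vector(D[rows, , drop = FALSE] %*% delta)
      }
      mat
    }
    state$psi_c <- upd_level(state$psi_c, cn, frame$rows_by_country, B,
                             frame$agg$BtB_c, state$sigma2_psi[, "c"])
    state$psi_r <- upd_level(state$psi_r, rg, frame$rows_by_region, B,
                             frame$agg$BtB_r, state$sigma2_psi[, "r"])
    state$psi_s <- upd_level(state$psi_s, sg, frame$rows_by_sregion, B,
                             frame$agg$BtB_s, state$sigma2_psi[, "s"])
    if (!is.null(state$phi_g)) {
      state$phi_c <- upd_level(state$phi_c, cn, frame$rows_by_country, Bt,
                               frame$agg$BtBt_c, state$sigma2_phi[, "c"])
      state$phi_r <- upd_level(state$phi_r, rg, frame$rows_by_region, Bt,
                               frame$agg$BtBt_r, state$sigma2_phi[, "r"])
      state$phi_s <- upd_level(state$phi_s, sg, frame$rows_by_sregion, Bt,
                               frame$agg$BtBt_s, state$sigma2_phi[, "s"])
    }
    # global coefficient vectors: flat prior, sampled on the identified
    # eigensubspace of the age design; null directions stay at zero
    state$psi_g <- draw_global_coef(state$psi_g, B, frame$B_eigen, r2, m_age, tau2)
    m_age_new <- rowSums(B * t(composite_psi(state, h))[cn, , drop = FALSE])
    if (!is.null(state$phi_g)) {
      m_age_tmp <- m_age_new + rowSums(Bt * t(composite_phi(state, h))[cn, , drop = FALSE])
      state$phi_g <- draw_global_coef(state$phi_g, Bt, frame$Bt_eigen, r2, m_age_tmp, tau2)
      m_age_new <- m_age_new + rowSums(Bt * t(composite_phi(state, h))[cn, , drop = FALSE])
    }
    m_age <- m_age_new
    mu <- m_ab + m_u + m_age + m_x + m_e
  }

  ## --- conjugate variances ---------------------------------------------------
  if ("variances" %in% blocks) {
    cp <- state$caps
    kup <- function(x, cap) max(rinvgamma_flatsd(length(x), sum(x^2), cap), VARIANCE_FLOOR)
    # tau2, kappa_ac and kappa_bc are updated by the collapsed Metropolis step
    if (frame$L >= 2) {
      state$kappa["ar"] <- kup(state$ar, cp$kappa["ar"])
      state$kappa["br"] <- kup(state$br, cp$kappa["br"])
    }
    if (frame$M >= 2) {
      state$kappa["as_"] <- kup(state$as_, cp$kappa["as_"])
      state$kappa["bs"] <- kup(state$bs, cp$kappa["bs"])
    }
    # the country-level columns of sigma2_psi / sigma2_phi are updated by the
    # collapsed Metropolis step, not conditionally on the coefficients
    for (k in 1:5) {
      if (frame$L >= 2) state$sigma2_psi[k, "r"] <- kup(state$psi_r[k, ], cp$sigma2_psi[k])
      if (frame$M >= 2) state$sigma2_psi[k, "s"] <- kup(state$psi_s[k, ], cp$sigma2_psi[k])
      if (!is.null(state$phi_g)) {
        if (frame$L >= 2) state$sigma2_phi[k, "r"] <- kup(state$phi_r[k, ], cp$sigma2_phi[k])
        if (frame$M >= 2) state$sigma2_phi[k, "s"] <- kup(state$phi_s[k, ], cp$sigma2_phi[k])
      }
    }
  }
  state
}

# draw from N(Q^{-1} b, Q^{-1}) robustly: solve in diagonally rescaled
# coordinates (unit-ish diagonal) and fall back to a spectral square root if
# the Cholesky still fails on a near-singular conditional
joint_gaussian_draw <- function(Q, b) {
  s <- sqrt(diag(Q))
  s[s <= 0 | !is.finite(s)] <- 1
  Qs <- Q / tcrossprod(s)
  bs <- as.vector(b) / s
  Rch <- tryCatch(chol(Qs), error = function(e) NULL)
  if (!is.null(Rch)) {
    x <- backsolve(Rch, forwardsolve(t(Rch), bs)) +
      backsolve(Rch, stats::rnorm(length(bs)))
  } else {
    e <- eigen(Qs, symmetric = TRUE)
    d <- pmax(e$values, max(e$values) * 1e-12)
    w <- as.vector(crossprod(e$vectors, bs)) / d
    x <- as.vector(e$vectors %*% (w + stats::rnorm(length(d)) / sqrt(d)))
  }
  as.vector(x) / s
}

# inverse-gamma draw for a variance with (truncated) flat-on-SD prior:
# w | SS ~ InvGamma(shape = (n-1)/2, rate = SS/2) restricted to
# lower <= w <= cap, drawn by inverse-CDF on the gamma scale of 1/w
rinvgamma_flatsd <- function(n, SS, cap = Inf, lower = 0) {
  shape <- (n - 1) / 2
  if (shape <= 0) stop("flat-on-SD variance update needs at least 2 components")
  rate <- SS / 2
  if (!is.finite(cap) && lower <= 0) return(rate / stats::rgamma(1, shape = shape))
  F0 <- stats::pgamma(1 / cap, shape = shape, rate = rate)
  F1 <- if (lower > 0) stats::pgamma(1 / lower, shape = shape, rate = rate) else 1
  g <- stats::qgamma(F0 + stats::runif(1) * (F1 - F0), shape = shape, rate = rate)
  if (!is.finite(g) || g <= 0) return(cap)
  min(max(rate / g, lower), cap)
}

# joint draw of a flat-prior global coefficient vector on the identified
# eigensubspace of its design cross product
draw_global_coef <- function(coef, D, De, r2, m_age, tau2) {
  contrib <- as.vector(D %*% coef)
  rr <- r2 - (m_age - contrib)
  keep <- De$values > max(De$values) * 1e-9
  V1 <- De$vectors[, keep, drop = FALSE]
  d <- De$values[keep]
  wmean <- as.vector(crossprod(V1, crossprod(D, rr))) / d
  w <- wmean + stats::rnorm(length(d)) * sqrt(tau2 / d)
  null_part <- coef - as.vector(V1 %*% crossprod(V1, coef))
  as.vector(V1 %*% w) + null_part
}

#' Metropolis step for the ordered / truncated variance parameters
#'
#' Partially collapsed random-walk Metropolis on the log scale. Each RW2
#' precision lambda is updated against its marginal likelihood with the
#' corresponding u vectors integrated out analytically (the Gaussian layer
#' admits this in closed form), after which the level's u vectors are redrawn
#' from their exact full conditionals; this breaks the funnel-shaped coupling
#' between a smoothing precision and its smoothed vectors. The study
#' random-effect variances v are treated the same way, integrating out the
#' study effects e and redrawing them afterwards. Proposals violating the
#' orderings lambda_c < lambda_r < lambda_s < lambda_g or v_n < v_s < v_c, or
#' the truncations, are rejected outright. Acceptance ratios include the log-
#' scale Jacobian together with the flat-on-SD priors.
#'
#' @param state a model state.
#' @param frame a [model_frame()].
#' @param ctrl list: `adapt` as in [gibbs_sweep()]; `vars` optionally
#'   restricts which hyperparameters are updated (subset of "lambda", "v",
#'   "kappa", "sigma", "tau2"; the collapsed-out blocks are redrawn either
#'   way, which keeps the move a valid conditional draw).
#' @return the updated state.
#' @export
mh_variance_step <- function(state, frame, ctrl = list()) {
  adapt <- isTRUE(ctrl$adapt)
  vars <- ctrl$vars %||% c("lambda", "v", "kappa", "sigma", "tau2")
  if (is.null(state$.tune)) state$.tune <- new_tuning(frame)
  gain <- 0.05
  tau2 <- state$tau2
  yr <- frame$year
  comp <- row_components(state, frame)
  m_u <- comp$m_u; m_e <- comp$m_e; mu <- comp$mu
  lam_min <- if (!is.null(state$caps)) state$caps$lambda_min else 0
  vcap <- if (!is.null(state$caps)) state$caps$v else Inf
  th <- log(state$lambda)

  ## --- lambda_r, lambda_s, lambda_g: collapsed over the level's u ----------
  r1 <- state$alpha - (mu - m_u)
  for (lv in u_level_spec(state, frame)) {
    if (lv$name == "uc" || !("lambda" %in% vars)) next
    Umat <- if (lv$name == "ug") matrix(state$ug, 1, frame$T) else state[[lv$name]]
    m_u_level <- Umat[cbind(lv$g, yr)]
    rlev <- r1 - (m_u - m_u_level)
    nunit <- nrow(Umat)
    ysums <- lapply(seq_len(nunit), function(u) year_sums(frame, lv$rows[[u]], rlev))
    bs <- lapply(ysums, function(ys) as.vector(crossprod(frame$V, ys)) / tau2)
    i <- lv$li
    marg <- function(lam) sum(vapply(seq_len(nunit), function(u)
      lambda_unit_marginal(frame, lv$G[[u]], lam, bs[[u]], tau2), 0.0))
    prop <- th[i] + exp(state$.tune$ls_lambda[i]) * stats::rnorm(1)
    thp <- th; thp[i] <- prop
    ok <- prop <= 20 && prop >= log(lam_min) && all(diff(thp) > 0)
    acc <- FALSE
    if (ok) {
      # prior lambda^(-3/2) plus the log-scale Jacobian gives -theta/2
      logr <- marg(exp(prop)) - marg(exp(th[i])) - (prop - th[i]) / 2
      acc <- log(stats::runif(1)) < logr
      if (acc) th[i] <- prop
    }
    state$.tune$acc_lambda[i] <- state$.tune$acc_lambda[i] + acc
    state$.tune$n_lambda[i] <- state$.tune$n_lambda[i] + 1
    if (adapt) state$.tune$ls_lambda[i] <- state$.tune$ls_lambda[i] + gain * (acc - 0.44)
    state$lambda[i] <- exp(th[i])
    # redraw the level's u from its exact conditional, completing the
    # partially collapsed update
    lam <- state$lambda[i]
    for (uidx in seq_len(nunit)) {
      rows <- lv$rows[[uidx]]
      un <- draw_u_subspace(frame, lv$G[[uidx]], lam, ysums[[uidx]], tau2)
      delta <- un - Umat[uidx, ]
      Umat[uidx, ] <- un
      if (length(rows)) m_u[rows] <- m_u[rows] + delta[yr[rows]]
    }
    if (lv$name == "ug") state$ug <- Umat[1, ] else state[[lv$name]] <- Umat
  }
  mu <- comp$m_ab + m_u + comp$m_age + comp$m_x + m_e

  ## --- country level: lambda_c, v's and the country-level spline variances,
  ## collapsed jointly over ALL country-level random blocks (u_c, e, psi_c,
  ## phi_c). These blocks compete for the same between-study signal; only the
  ## joint marginal resolves the allocation instead of letting whichever
  ## block is updated first absorb it.
  adult <- !is.null(state$phi_g)
  m_u_c <- state$uc[cbind(frame$country, yr)]
  m_psi_c <- rowSums(frame$B * t(state$psi_c)[frame$country, , drop = FALSE])
  m_phi_c <- if (adult)
    rowSums(frame$Bt * t(state$phi_c)[frame$country, , drop = FALSE]) else 0
  m_ab_c <- state$ac[frame$country] + state$bc[frame$country] * frame$tc
  r_cty <- state$alpha - (mu - m_u_c - m_e - m_psi_c - m_phi_c - m_ab_c)
  rj <- lapply(frame$cmarg, function(cm) if (is.null(cm)) NULL else r_cty[cm$rows])
  tcj <- lapply(frame$cmarg, function(cm) if (is.null(cm)) NULL else frame$tc[cm$rows])

  country_ml <- function(lam_c, v, s2psi, s2phi, ka, kb, t2 = tau2) {
    tot <- 0
    for (j in seq_along(frame$cmarg)) {
      cm <- frame$cmarg[[j]]
      if (is.null(cm)) next
      C <- cm$K / lam_c + ka + kb * tcrossprod(tcj[[j]]) +
        cm$Bj %*% (s2psi * t(cm$Bj))
      if (adult) C <- C + cm$Btj %*% (s2phi * t(cm$Btj))
      for (gix in seq_along(cm$study_groups)) {
        gidx <- cm$study_groups[[gix]]
        C[gidx, gidx] <- C[gidx, gidx] + v[cm$study_class[gix]]
      }
      diag(C) <- diag(C) + t2
      Rch <- chol(C)
      z <- forwardsolve(t(Rch), rj[[j]])
      tot <- tot - sum(log(diag(Rch))) - sum(z^2) / 2
    }
    tot
  }
  s2psi <- state$sigma2_psi[, "c"]
  s2phi <- if (adult) state$sigma2_phi[, "c"] else NULL
  ka <- unname(state$kappa["ac"]); kb <- unname(state$kappa["bc"])
  ml_cur <- country_ml(state$lambda[1], state$v, s2psi, s2phi, ka, kb)

  # tau2: collapsed over the country-level blocks (it enters the marginal on
  # the diagonal); flat-on-SD prior truncated to [tau2_min, tau2 cap]
  if (!is.null(state$caps) && "tau2" %in% vars) {
    ls <- state$.tune$ls_tau
    prop <- log(tau2) + exp(ls) * stats::rnorm(1)
    acc <- FALSE
    if (prop <= log(state$caps$tau2) && prop >= log(state$caps$tau2_min)) {
      ml_prop <- country_ml(state$lambda[1], state$v, s2psi, s2phi, ka, kb,
                            t2 = exp(prop))
      logr <- ml_prop - ml_cur + (prop - log(tau2)) / 2
      acc <- log(stats::runif(1)) < logr
      if (acc) {
        state$tau2 <- exp(prop)
        tau2 <- state$tau2
        ml_cur <- ml_prop
      }
    }
    state$.tune$acc_tau <- state$.tune$acc_tau + acc
    state$.tune$n_tau <- state$.tune$n_tau + 1
    if (adapt) state$.tune$ls_tau <- ls + gain * (acc - 0.44)
  }

  # kappa_ac, kappa_bc: collapsed over the country intercepts and slopes;
  # flat-on-SD prior gives +theta/2 with the log-scale Jacobian
  if (frame$J >= 2 && "kappa" %in% vars) {
    cpk <- if (!is.null(state$caps)) state$caps$kappa else c(ac = Inf, bc = Inf)
    for (i in 1:2) {
      cur <- if (i == 1) ka else kb
      ls <- state$.tune$ls_kappa_c[i]
      prop <- log(cur) + exp(ls) * stats::rnorm(1)
      cap <- if (i == 1) cpk["ac"] else cpk["bc"]
      acc <- FALSE
      if (prop <= log(cap) && prop >= log(VARIANCE_FLOOR)) {
        ml_prop <- if (i == 1) country_ml(state$lambda[1], state$v, s2psi, s2phi, exp(prop), kb)
                   else country_ml(state$lambda[1], state$v, s2psi, s2phi, ka, exp(prop))
        logr <- ml_prop - ml_cur + (prop - log(cur)) / 2
        acc <- log(stats::runif(1)) < logr
        if (acc) {
          if (i == 1) ka <- exp(prop) else kb <- exp(prop)
          ml_cur <- ml_prop
        }
      }
      state$.tune$acc_kappa_c[i] <- state$.tune$acc_kappa_c[i] + acc
      state$.tune$n_kappa_c[i] <- state$.tune$n_kappa_c[i] + 1
      if (adapt) state$.tune$ls_kappa_c[i] <- ls + gain * (acc - 0.44)
    }
    state$kappa["ac"] <- ka; state$kappa["bc"] <- kb
  }

  # lambda_c: the covariance-form marginal already carries the RW2
  # normalizer; prior lambda^(-3/2) plus the log-scale Jacobian gives -theta/2
  prop <- th[1] + exp(state$.tune$ls_lambda[1]) * stats::rnorm(1)
  thp <- th; thp[1] <- prop
  ok <- "lambda" %in% vars && prop <= 20 && prop >= log(lam_min) && all(diff(thp) > 0)
  acc <- FALSE
  if (ok) {
    ml_prop <- country_ml(exp(prop), state$v, s2psi, s2phi, ka, kb)
    logr <- ml_prop - ml_cur - (prop - th[1]) / 2
    acc <- log(stats::runif(1)) < logr
    if (acc) { th[1] <- prop; state$lambda[1] <- exp(prop); ml_cur <- ml_prop }
  }
  state$.tune$acc_lambda[1] <- state$.tune$acc_lambda[1] + acc
  state$.tune$n_lambda[1] <- state$.tune$n_lambda[1] + 1
  if (adapt) state$.tune$ls_lambda[1] <- state$.tune$ls_lambda[1] + gain * (acc - 0.44)

  # v's: prior v^(-1/2) plus the Jacobian gives +theta/2
  thv <- log(state$v)
  for (i in 1:3) {
    if (!("v" %in% vars)) break
    prop <- thv[i] + exp(state$.tune$ls_v[i]) * stats::rnorm(1)
    thp <- thv; thp[i] <- prop
    ok <- all(diff(thp) > 0) && prop <= log(vcap)
    acc <- FALSE
    if (ok) {
      ml_prop <- country_ml(state$lambda[1], exp(thp), s2psi, s2phi, ka, kb)
      logr <- ml_prop - ml_cur + (prop - thv[i]) / 2
      acc <- log(stats::runif(1)) < logr
      if (acc) { thv[i] <- prop; state$v[i] <- exp(prop); ml_cur <- ml_prop }
    }
    state$.tune$acc_v[i] <- state$.tune$acc_v[i] + acc
    state$.tune$n_v[i] <- state$.tune$n_v[i] + 1
    if (adapt) state$.tune$ls_v[i] <- state$.tune$ls_v[i] + gain * (acc - 0.44)
  }

  # country-level spline variances: same collapsed treatment, flat-on-SD
  # priors truncated at the caps
  if (frame$J >= 2 && "sigma" %in% vars) {
    cp_psi <- if (!is.null(state$caps)) state$caps$sigma2_psi else rep(Inf, 5)
    for (k in 1:5) {
      ls <- state$.tune$ls_sig_psi[k]
      thk <- log(s2psi[k])
      prop <- thk + exp(ls) * stats::rnorm(1)
      acc <- FALSE
      if (prop <= log(cp_psi[k]) && prop >= log(VARIANCE_FLOOR)) {
        sp <- s2psi; sp[k] <- exp(prop)
        ml_prop <- country_ml(state$lambda[1], state$v, sp, s2phi, ka, kb)
        logr <- ml_prop - ml_cur + (prop - thk) / 2
        acc <- log(stats::runif(1)) < logr
        if (acc) { s2psi <- sp; ml_cur <- ml_prop }
      }
      state$.tune$acc_sig[k] <- state$.tune$acc_sig[k] + acc
      state$.tune$n_sig[k] <- state$.tune$n_sig[k] + 1
      if (adapt) state$.tune$ls_sig_psi[k] <- ls + gain * (acc - 0.44)
    }
    state$sigma2_psi[, "c"] <- s2psi
    if (adult) {
      cp_phi <- if (!is.null(state$caps)) state$caps$sigma2_phi else rep(Inf, 5)
      for (k in 1:5) {
        ls <- state$.tune$ls_sig_phi[k]
        thk <- log(s2phi[k])
        prop <- thk + exp(ls) * stats::rnorm(1)
        acc <- FALSE
        if (prop <= log(cp_phi[k]) && prop >= log(VARIANCE_FLOOR)) {
          sp <- s2phi; sp[k] <- exp(prop)
          ml_prop <- country_ml(state$lambda[1], state$v, s2psi, sp, ka, kb)
          logr <- ml_prop - ml_cur + (prop - thk) / 2
          acc <- log(stats::runif(1)) < logr
          if (acc) { s2phi <- sp; ml_cur <- ml_prop }
        }
        state$.tune$acc_sig[5 + k] <- state$.tune$acc_sig[5 + k] + acc
        state$.tune$n_sig[5 + k] <- state$.tune$n_sig[5 + k] + 1
        if (adapt) state$.tune$ls_sig_phi[k] <- ls + gain * (acc - 0.44)
      }
      state$sigma2_phi[, "c"] <- s2phi
    }
  }

  # redraw the collapsed blocks in conditional sequence:
  # (ac, bc) | (u_c, psi_c, phi_c, e marginal), u_c | ac, bc (rest marginal),
  # psi_c | ..., phi_c | ..., then e | everything
  lam_c <- state$lambda[1]
  for (j in seq_len(frame$J)) {
    cm <- frame$cmarg[[j]]
    if (is.null(cm)) {
      state$ac[j] <- stats::rnorm(1, 0, sqrt(ka))
      state$bc[j] <- stats::rnorm(1, 0, sqrt(kb))
      state$uc[j, ] <- rconstrained_rw2(frame$P_eigen, lam_c)
      state$psi_c[, j] <- stats::rnorm(5, 0, sqrt(s2psi))
      if (adult) state$phi_c[, j] <- stats::rnorm(5, 0, sqrt(s2phi))
      next
    }
    nr <- length(cm$rows)
    vblocks <- matrix(0, nr, nr)
    for (gix in seq_along(cm$study_groups)) {
      gidx <- cm$study_groups[[gix]]
      vblocks[gidx, gidx] <- vblocks[gidx, gidx] + state$v[cm$study_class[gix]]
    }
    base <- vblocks; diag(base) <- diag(base) + tau2
    Cu <- cm$K / lam_c
    Cpsi <- cm$Bj %*% (s2psi * t(cm$Bj))
    Cphi <- if (adult) cm$Btj %*% (s2phi * t(cm$Btj)) else 0
    # (ac, bc) jointly: design [1, tc], priors diag(1/ka, 1/kb)
    Aab <- cbind(1, tcj[[j]])
    W <- chol2inv(chol(base + Cu + Cpsi + Cphi))
    Mab <- crossprod(Aab, W %*% Aab) + diag(c(1 / ka, 1 / kb))
    bab <- crossprod(Aab, W %*% rj[[j]])
    abj <- joint_gaussian_draw(Mab, bab)
    state$ac[j] <- abj[1]; state$bc[j] <- abj[2]
    r2j <- rj[[j]] - Aab %*% abj
    # u_c
    W <- chol2inv(chol(base + Cpsi + Cphi))
    Mw <- crossprod(cm$Vj, W %*% cm$Vj)
    diag(Mw) <- diag(Mw) + lam_c * frame$Dvals
    bw <- crossprod(cm$Vj, W %*% r2j)
    Rch <- chol(Mw)
    w <- backsolve(Rch, forwardsolve(t(Rch), bw)) +
      backsolve(Rch, stats::rnorm(length(frame$Dvals)))
    state$uc[j, ] <- as.vector(frame$V %*% w)
    r2j <- r2j - cm$Vj %*% w
    # psi_c
    W <- chol2inv(chol(base + Cphi))
    Mp <- crossprod(cm$Bj, W %*% cm$Bj) + diag(1 / s2psi)
    bp <- crossprod(cm$Bj, W %*% r2j)
    state$psi_c[, j] <- joint_gaussian_draw(Mp, bp)
    r2j <- r2j - cm$Bj %*% state$psi_c[, j]
    # phi_c
    if (adult) {
      W <- chol2inv(chol(base))
      Mf <- crossprod(cm$Btj, W %*% cm$Btj) + diag(1 / s2phi)
      bf <- crossprod(cm$Btj, W %*% r2j)
      state$phi_c[, j] <- joint_gaussian_draw(Mf, bf)
    }
  }
  # e | everything else (exact conditional under the redrawn blocks)
  comp <- row_components(state, frame)
  re <- state$alpha - (comp$mu - comp$m_e)
  sums <- rowsum(re, frame$study)
  sums_full <- numeric(frame$n_study)
  sums_full[as.integer(rownames(sums))] <- sums
  ni <- frame$agg$cnt_study
  prec <- ni / tau2 + 1 / state$v[frame$study_coverage]
  state$e <- stats::rnorm(frame$n_study, (sums_full / tau2) / prec, sqrt(1 / prec))
  state
}
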