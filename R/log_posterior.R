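#' Log posterior density of a model state
#'
#' Sum of (i) the binomial log likelihood of the counts given prevalence
#' Phi(alpha); (ii) the Gaussian density of each alpha around its latent mean
#' with variance tau2; (iii) Gaussian hierarchical terms for the a, b, psi and
#' phi components around zero with their kappa / sigma2 variances; (iv) the
#' constrained RW2 terms, per vector, ((T-2)/2) log(lambda) - (lambda/2)
#' u' P u; (v) Gaussian study random-effect terms with coverage-dependent
#' variances; and (vi) the flat-on-standard-deviation hyperpriors, which
#' contribute -log(sigma) = -(1/2) log(variance) for each variance and
#' -(3/2) log(lambda) for each RW2 precision. Global intercepts, slopes and
#' spline coefficients carry flat priors and contribute nothing. Additive
#' constants that do not involve parameters are dropped. Returns -Inf for
#' states outside the prior support (ordering or truncation violated).
#'
#' @param state a [new_model_state()].
#' @param frame a [model_frame()].
#' @return a single numeric value (possibly -Inf).
#' @export
log_posterior <- function(state, frame) {
  if (!state_in_support(state)) return(-Inf)
  if (length(state$alpha) != frame$R) stop("alpha has wrong length for this frame")
  mu <- latent_mean(state, frame)
  p <- stats::pnorm(state$alpha)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  lp <- sum(stats::dbinom(frame$y, frame$n, p, log = TRUE))
  lp <- lp + sum(stats::dnorm(state$alpha, mu, sqrt(state$tau2), log = TRUE))

  # hierarchical linear components
  lp <- lp + sum(stats::dnorm(state$ac, 0, sqrt(state$kappa["ac"]), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$ar, 0, sqrt(state$kappa["ar"]), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$as_, 0, sqrt(state$kappa["as_"]), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$bc, 0, sqrt(state$kappa["bc"]), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$br, 0, sqrt(state$kappa["br"]), log = TRUE))
  lp <- lp + sum(stats::dnorm(state$bs, 0, sqrt(state$kappa["bs"]), log = TRUE))

  # constrained RW2 components: rank-(T-2) density per vector
  P <- frame$P; Tm2 <- (frame$T - 2) / 2
  quad <- function(U) if (is.matrix(U)) sum(apply(U, 1, function(u) sum(u * (P %*% u)))) else sum(U * (P %*% U))
  nvec <- c(frame$J, frame$L, frame$M, 1)
  qs <- c(quad(state$uc), quad(state$ur), quad(state$us), quad(state$ug))
  lp <- lp + sum(nvec * Tm2 * log(state$lambda) - state$lambda / 2 * qs)

  # spline coefficient hierarchies
  for (k in 1:5) {
    lp <- lp + sum(stats::dnorm(state$psi_c[k, ], 0, sqrt(state$sigma2_psi[k, "c"]), log = TRUE)) +
      sum(stats::dnorm(state$psi_r[k, ], 0, sqrt(state$sigma2_psi[k, "r"]), log = TRUE)) +
      sum(stats::dnorm(state$psi_s[k, ], 0, sqrt(state$sigma2_psi[k, "s"]), log = TRUE))
    if (!is.null(state$phi_g)) {
      lp <- lp + sum(stats::dnorm(state$phi_c[k, ], 0, sqrt(state$sigma2_phi[k, "c"]), log = TRUE)) +
        sum(stats::dnorm(state$phi_r[k, ], 0, sqrt(state$sigma2_phi[k, "r"]), log = TRUE)) +
        sum(stats::dnorm(state$phi_s[k, ], 0, sqrt(state$sigma2_phi[k, "s"]), log = TRUE))
    }
  }

  # study random effects, coverage-dependent variance
  vstudy <- state$v[frame$study_coverage]
  lp <- lp + sum(stats::dnorm(state$e, 0, sqrt(vstudy), log = TRUE))

  # flat-on-SD hyperpriors: p(variance) propto variance^(-1/2);
  # lambda: flat on 1/sqrt(lambda) gives p(lambda) propto lambda^(-3/2)
  lp <- lp - 0.5 * (sum(log(state$kappa)) + sum(log(state$sigma2_psi)) +
                      sum(log(state$v)) + log(state$tau2))
  if (!is.null(state$sigma2_phi)) lp <- lp - 0.5 * sum(log(state$sigma2_phi))
  lp <- lp - 1.5 * sum(log(state$lambda))
  lp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
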