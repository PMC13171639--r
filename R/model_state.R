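#' Model frame: observation rows prepared for the sampler
#'
#' Precomputes everything the latent-mean arithmetic and the sampler need:
#' integer country/region/super-region/study/year indices per row, centered
#' time, the age spline basis, the study-design matrix, the RW2 penalty matrix
#' and its eigendecomposition, and row-index lists by hierarchy level. Time is
#' centered at the midpoint of the estimation window before entering slopes
#' and slope interactions; the centering constant is stored so predictions are
#' unambiguous.
#'
#' @param obs observation table with columns study_id, country (integer,
#'   1..J), year (integer, 1..T), mid_age, category (single category),
#'   y, n, coverage, urban_scope, country_urbanization.
#' @param hierarchy a [hierarchy_spec()].
#' @param T number of years in the estimation window.
#' @param population "adult" (age-time interactions present) or
#'   "child_adolescent" (no age-time interactions, structurally).
#' @param knots spline knots; default (45, 60) for adults, (10, 15) for
#'   children.
#' @param age_center age-centering constant; default 50 (adult) / 12 (child).
#' @return an object of class "model_frame".
#' @export
model_frame <- function(obs, hierarchy, T,
                        population = c("adult", "child_adolescent"),
                        knots = NULL, age_center = NULL) {
  population <- match.arg(population)
  stopifnot(inherits(hierarchy, "hierarchy_spec"))
  need <- c("study_id", "country", "year", "mid_age", "y", "n",
            "coverage", "urban_scope", "country_urbanization")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("obs is missing columns: ", paste(miss, collapse = ", "))
  if (any(obs$n <= 0) || any(obs$y < 0) || any(obs$y > obs$n))
    stop("observation rows must satisfy 0 <= y <= n, n > 0")
  if (any(obs$country < 1L | obs$country > hierarchy$J))
    stop("unknown country index in observation table")
  if (any(obs$year < 1L | obs$year > T)) stop("year outside 1..T")
  if (is.null(knots)) knots <- if (population == "adult") c(45, 60) else c(10, 15)
  if (is.null(age_center)) age_center <- if (population == "adult") 50 else 12

  country <- as.integer(obs$country)
  region <- hierarchy$region_of[country]
  sregion <- hierarchy$sregion_of_country[country]
  year <- as.integer(obs$year)
  t_center <- (T + 1) / 2
  tc <- year - t_center
  study <- as.integer(factor(obs$study_id, levels = unique(obs$study_id)))
  S <- max(study)
  first <- match(seq_len(S), study)
  cov_code <- match(obs$coverage[first], c("national", "subnational", "community"))
  if (anyNA(cov_code)) stop("coverage must be national/subnational/community")
  X <- t(mapply(study_design_vector,
                obs$coverage, obs$urban_scope, tc, obs$country_urbanization))
  dimnames(X) <- NULL
  B <- age_spline_basis(obs$mid_age, knots, age_center)

  frame <- list(
    y = as.numeric(obs$y), n = as.numeric(obs$n),
    R = nrow(obs), J = hierarchy$J, L = hierarchy$L, M = hierarchy$M, T = as.integer(T),
    hierarchy = hierarchy, population = population,
    knots = knots, age_center = age_center, t_center = t_center,
    country = country, region = region, sregion = sregion,
    year = year, tc = tc, study = study, n_study = S,
    study_country = country[first], study_coverage = cov_code,
    X = X, B = B,
    P = rw2_penalty_matrix(T),
    P_eigen = rw2_penalty_eigen(T),
    rows_by_country = split(seq_len(nrow(obs)), factor(country, levels = seq_len(hierarchy$J))),
    rows_by_region = split(seq_len(nrow(obs)), factor(region, levels = seq_len(hierarchy$L))),
    rows_by_sregion = split(seq_len(nrow(obs)), factor(sregion, levels = seq_len(hierarchy$M))),
    rows_by_study = split(seq_len(nrow(obs)), study),
    obs = obs)
  class(frame) <- "model_frame"
  frame_add_aggregates(frame)
}

# Precomputed aggregates used by the full-conditional updates: counts and
# fixed-design sums of squares by hierarchy level, per-unit year counts for
# the RW2 conditionals, and eigendecompositions of the age-design cross
# products (whose null spaces, when the observed age grid is coarser than the
# basis, are the non-identified directions pinned at zero).
frame_add_aggregates <- function(frame) {
  J <- frame$J; L <- frame$L; M <- frame$M; T <- frame$T
  gsum <- function(x, g, nlev) {
    out <- numeric(nlev)
    s <- rowsum(x, g)
    out[as.integer(rownames(s))] <- s
    out
  }
  tc2 <- frame$tc^2
  one <- rep(1, frame$R)
  frame$agg <- list(
    cnt_c = gsum(one, frame$country, J),
    cnt_r = gsum(one, frame$region, L),
    cnt_s = gsum(one, frame$sregion, M),
    tc2_c = gsum(tc2, frame$country, J),
    tc2_r = gsum(tc2, frame$region, L),
    tc2_s = gsum(tc2, frame$sregion, M),
    tc2_g = sum(tc2),
    cnt_study = gsum(one, frame$study, frame$n_study))
  Bt <- frame$B * frame$tc
  frame$Bt <- Bt
  frame$B_eigen <- eigen(crossprod(frame$B), symmetric = TRUE)
  frame$Bt_eigen <- eigen(crossprod(Bt), symmetric = TRUE)
  xp <- function(D, rows_list) lapply(rows_list, function(r)
    crossprod(D[r, , drop = FALSE]))
  frame$agg$BtB_c <- xp(frame$B, frame$rows_by_country)
  frame$agg$BtB_r <- xp(frame$B, frame$rows_by_region)
  frame$agg$BtB_s <- xp(frame$B, frame$rows_by_sregion)
  frame$agg$BtBt_c <- xp(Bt, frame$rows_by_country)
  frame$agg$BtBt_r <- xp(Bt, frame$rows_by_region)
  frame$agg$BtBt_s <- xp(Bt, frame$rows_by_sregion)
  frame$beta_idx <- which(colSums(abs(frame$X)) > 1e-12)
  ycount <- function(rows_list, nunit) {
    out <- matrix(0, nunit, T)
    for (u in seq_len(nunit)) {
      r <- rows_list[[u]]
      if (length(r)) {
        tb <- table(frame$year[r])
        out[u, as.integer(names(tb))] <- as.numeric(tb)
      }
    }
    out
  }
  frame$agg$ycnt_c <- ycount(frame$rows_by_country, J)
  frame$agg$ycnt_r <- ycount(frame$rows_by_region, L)
  frame$agg$ycnt_s <- ycount(frame$rows_by_sregion, M)
  frame$agg$ycnt_g <- matrix(colSums(frame$agg$ycnt_c), 1, T)
  frame$agg$ndist_c <- rowSums(frame$agg$ycnt_c > 0)
  frame$agg$ndist_r <- rowSums(frame$agg$ycnt_r > 0)
  frame$agg$ndist_s <- rowSums(frame$agg$ycnt_s > 0)
  frame$agg$ndist_g <- sum(colSums(frame$agg$ycnt_c) > 0)
  # RW2 subspace machinery: the constrained prior (zero mean and slope) lives
  # exactly on the span of the penalty's non-null eigenvectors; per-unit
  # Gram matrices V' diag(year counts) V are fixed across sweeps
  V <- frame$P_eigen$vectors[, frame$P_eigen$nonnull, drop = FALSE]
  frame$V <- V
  frame$Dvals <- frame$P_eigen$values[frame$P_eigen$nonnull]
  gram <- function(ycnt) lapply(seq_len(nrow(ycnt)), function(u)
    crossprod(V * sqrt(ycnt[u, ])))
  frame$agg$G_c <- gram(frame$agg$ycnt_c)
  frame$agg$G_r <- gram(frame$agg$ycnt_r)
  frame$agg$G_s <- gram(frame$agg$ycnt_s)
  frame$agg$G_g <- gram(frame$agg$ycnt_g)
  # per-country pieces for the jointly collapsed (lambda_c, v) updates:
  # row-selected subspace basis, unit-precision RW2 covariance kernel, and
  # study blocks with their coverage classes
  frame$cmarg <- lapply(seq_len(J), function(j) {
    rows <- frame$rows_by_country[[j]]
    if (!length(rows)) return(NULL)
    Vj <- V[frame$year[rows], , drop = FALSE]
    K <- tcrossprod(sweep(Vj, 2, sqrt(frame$P_eigen$values[frame$P_eigen$nonnull]), "/"))
    studs <- frame$study[rows]
    sg <- split(seq_along(rows), studs)
    list(rows = rows, Vj = Vj, K = K,
         Bj = frame$B[rows, , drop = FALSE],
         Btj = Bt[rows, , drop = FALSE],
         study_groups = sg,
         study_class = frame$study_coverage[as.integer(names(sg))],
         study_ids = as.integer(names(sg)))
  })
  frame
}

#' Construct a model state
#'
#' Holds every latent parameter of the model: hierarchical linear trend
#' components (a, b at country/region/super-region/global levels with
#' variances kappa), RW2 nonlinear components u at the four levels with
#' precisions lambda, spline coefficient components psi (and, for adults,
#' their time slopes phi) with variances sigma2, study offsets beta, study
#' random effects e with coverage-dependent variances v, the residual
#' age-by-study variance tau2, and the latent probit prevalences alpha.
#' All values default to a zeroed state with weakly dispersed, ordering-valid
#' variances.
#'
#' All flat-on-SD variance priors are truncated above at generous caps (a
#' computational-convenience device, like the log lambda <= 20 truncation):
#' intercept variances at 100, slope variances at 1, study-effect and
#' residual variances at 25, and spline-coefficient variances at
#' (10 / scale_k)^2 where scale_k is the root-mean-square of basis column k,
#' so that age-term contributions stay bounded on the probit scale even in
#' directions the observed age grid cannot identify.
#'
#' @param frame a [model_frame()].
#' @param init optional named list overriding individual blocks.
#' @return an object of class "model_state".
#' @export
new_model_state <- function(frame, init = list()) {
  J <- frame$J; L <- frame$L; M <- frame$M; T <- frame$T
  bscale <- pmax(sqrt(colMeans(frame$B^2)), 1e-12)
  btscale <- pmax(sqrt(colMeans((frame$B * frame$tc)^2)), 1e-12)
  # flat-on-SD priors truncated to an epidemiologically plausible range on
  # the probit scale: intercept spreads up to sd 2, slope spreads up to sd
  # 0.1/year, age-term contributions up to RMS 1 (0.5 for the age-time
  # interaction over the window), study effects and residual variability up
  # to sd 0.5
  # additionally: residual age-by-study SD at least 0.01 (surveys never agree
  # to better than that on the probit scale), and RW2 second-difference SD at
  # most 0.03 per year^2 (smooth national trends), i.e. lambda >= 1/0.03^2
  caps <- list(kappa = c(ac = 4, ar = 4, as_ = 4, bc = 0.01, br = 0.01, bs = 0.01),
               sigma2_psi = (1 / bscale)^2,
               sigma2_phi = (0.5 / btscale)^2,
               v = 0.25, tau2 = 0.25, tau2_min = 1e-4,
               lambda_min = 1 / 0.03^2)
  st <- list(
    caps = caps,
    ag = 0, bg = 0,
    ac = numeric(J), ar = numeric(L), as_ = numeric(M),
    bc = numeric(J), br = numeric(L), bs = numeric(M),
    kappa = c(ac = 0.05, ar = 0.05, as_ = 0.05, bc = 1e-3, br = 1e-3, bs = 1e-3),
    uc = matrix(0, J, T), ur = matrix(0, L, T), us = matrix(0, M, T), ug = numeric(T),
    lambda = c(c = 2000, r = 4000, s = 8000, g = 16000),
    psi_g = numeric(5), psi_c = matrix(0, 5, J), psi_r = matrix(0, 5, L),
    psi_s = matrix(0, 5, M),
    sigma2_psi = matrix((0.05 / bscale)^2, 5, 3,
                        dimnames = list(NULL, c("c", "r", "s"))),
    beta = numeric(8),
    e = numeric(frame$n_study),
    v = c(n = 0.005, s = 0.01, c = 0.02),
    tau2 = 0.01,
    alpha = numeric(frame$R),
    population = frame$population)
  if (frame$population == "adult") {
    st$phi_g <- numeric(5)
    st$phi_c <- matrix(0, 5, J); st$phi_r <- matrix(0, 5, L); st$phi_s <- matrix(0, 5, M)
    st$sigma2_phi <- matrix((0.01 / btscale)^2, 5, 3,
                            dimnames = list(NULL, c("c", "r", "s")))
  }
  for (nm in names(init)) st[[nm]] <- init[[nm]]
  class(st) <- "model_state"
  st
}

#' Check that a state lies in the prior support
#'
#' Verifies the ordering constraints lambda_c < lambda_r < lambda_s <
#' lambda_g, v_n < v_s < v_c, the truncation log(lambda) <= 20, and
#' positivity of all variances.
#'
#' @param state a model state.
#' @return TRUE if in support, FALSE otherwise.
#' @export
state_in_support <- function(state) {
  la <- state$lambda; v <- state$v
  ok <- all(la > 0) && la[1] < la[2] && la[2] < la[3] && la[3] < la[4] &&
    all(log(la) <= 20) &&
    all(v > 0) && v[1] < v[2] && v[2] < v[3] &&
    state$tau2 > 0 && all(state$kappa > 0) && all(state$sigma2_psi > 0)
  if (!is.null(state$sigma2_phi)) ok <- ok && all(state$sigma2_phi > 0)
  if (!is.null(state$caps)) {
    cp <- state$caps
    ok <- ok && all(state$kappa <= cp$kappa) && all(v <= cp$v) &&
      state$tau2 <= cp$tau2 && state$tau2 >= cp$tau2_min &&
      all(la >= cp$lambda_min) &&
      all(state$sigma2_psi <= cp$sigma2_psi)
    if (!is.null(state$sigma2_phi)) ok <- ok && all(state$sigma2_phi <= cp$sigma2_phi)
  }
  isTRUE(ok)
}

# Project a state's variance parameters into the truncated prior support:
# clamp to the caps and re-enforce the orderings by sorting.
clamp_to_support <- function(state) {
  cp <- state$caps
  state$kappa <- pmin(pmax(state$kappa, VARIANCE_FLOOR), cp$kappa)
  state$tau2 <- min(max(state$tau2, cp$tau2_min), cp$tau2)
  state$v <- sort(pmin(pmax(state$v, VARIANCE_FLOOR), cp$v))
  if (any(duplicated(state$v))) state$v <- state$v * c(0.98, 0.99, 1.0)
  la <- sort(pmin(pmax(state$lambda, cp$lambda_min * c(1.03, 1.02, 1.01, 1)), exp(20)))
  if (any(duplicated(la))) la <- la * c(0.94, 0.96, 0.98, 1.0)
  state$lambda[] <- la
  state$sigma2_psi <- pmin(pmax(state$sigma2_psi, VARIANCE_FLOOR), cp$sigma2_psi)
  if (!is.null(state$sigma2_phi))
    state$sigma2_phi <- pmin(pmax(state$sigma2_phi, VARIANCE_FLOOR), cp$sigma2_phi)
  state
}

# Composite country-level quantities -----------------------------------------

composite_a <- function(st, h) st$ac + st$ar[h$region_of] + st$as_[h$sregion_of_country] + st$ag
composite_b <- function(st, h) st$bc + st$br[h$region_of] + st$bs[h$sregion_of_country] + st$bg
composite_u <- function(st, h) {
  st$uc + st$ur[h$region_of, , drop = FALSE] +
    st$us[h$sregion_of_country, , drop = FALSE] +
    matrix(st$ug, nrow = h$J, ncol = length(st$ug), byrow = TRUE)
}
composite_psi <- function(st, h) {
  st$psi_c + st$psi_r[, h$region_of, drop = FALSE] +
    st$psi_s[, h$sregion_of_country, drop = FALSE] + st$psi_g
}
composite_phi <- function(st, h) {
  if (is.null(st$phi_g)) return(NULL)
  st$phi_c + st$phi_r[, h$region_of, drop = FALSE] +
    st$phi_s[, h$sregion_of_country, drop = FALSE] + st$phi_g
}

#' Latent probit-scale mean for observation rows
#'
#' Computes, per row, the mean of the latent probit prevalence:
#' a_j + b_j t + u_{j,t} + gamma_i(z_h) + X_i beta + e_i, where the age term
#' gamma combines the spline intercept coefficients psi and (for adults) the
#' time-slope coefficients phi, all composed across hierarchy levels.
#'
#' @param state a [new_model_state()].
#' @param frame a [model_frame()].
#' @param rows optional integer row subset.
#' @return numeric vector of probit-scale means.
#' @export
latent_mean <- function(state, frame, rows = NULL) {
  h <- frame$hierarchy
  if (is.null(rows)) rows <- seq_len(frame$R)
  a <- composite_a(state, h); b <- composite_b(state, h)
  U <- composite_u(state, h)
  psi <- composite_psi(state, h)   # 5 x J
  phi <- composite_phi(state, h)
  cn <- frame$country[rows]; tc <- frame$tc[rows]; yr <- frame$year[rows]
  Bm <- frame$B[rows, , drop = FALSE]
  m <- a[cn] + b[cn] * tc + U[cbind(cn, yr)] +
    rowSums(Bm * t(psi)[cn, , drop = FALSE]) +
    as.vector(frame$X[rows, , drop = FALSE] %*% state$beta) +
    state$e[frame$study[rows]]
  if (!is.null(phi)) m <- m + rowSums(Bm * t(phi)[cn, , drop = FALSE]) * tc
  m
}

#' Serialize a model state to a columnar table
#'
#' Flattens a state into a (block, level, index, value) data frame, the
#' checkpoint format. [table_to_state()] inverts it.
#'
#' @param state a model state.
#' @return data frame with columns block, level, index, value.
#' @export
state_to_table <- function(state) {
  rows <- list()
  flat <- function(block, level, x) {
    data.frame(block = block, level = level, index = seq_along(x),
               value = as.numeric(x), stringsAsFactors = FALSE)
  }
  for (nm in setdiff(names(state), c("population", "caps", ".tune"))) {
    x <- state[[nm]]
    rows[[nm]] <- flat(nm, "", x)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "population") <- state$population
  out
}

#' Rebuild a model state from its columnar table
#'
#' @param tab a table produced by [state_to_table()].
#' @param template a state with the correct shapes (from [new_model_state()]).
#' @return a model_state.
#' @export
table_to_state <- function(tab, template) {
  st <- template
  for (nm in unique(tab$block)) {
    vals <- tab$value[tab$block == nm][order(tab$index[tab$block == nm])]
    x <- st[[nm]]
    if (is.matrix(x)) st[[nm]] <- matrix(vals, nrow(x), ncol(x)) else {
      names(vals) <- names(x)
      st[[nm]] <- if (length(vals) == 1 && is.null(names(x))) as.numeric(vals) else vals
    }
  }
  class(st) <- "model_state"
  st
}
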