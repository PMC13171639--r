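#' Configuration of the synthetic survey world
#'
#' Describes the generative conditions for a synthetic multi-country survey
#' database with the exact structure the model assumes: hierarchical linear
#' country trends, constrained RW2 nonlinear change at all four levels, a
#' spline age pattern with hierarchical coefficients, study-design offsets,
#' coverage-dependent study random effects, residual age-by-study noise and
#' binomial sampling. Defaults give a reduced-scale world (12 countries in 4
#' regions in 2 super-regions, 25 years, 3 age groups, 3 studies per country)
#' whose probit-scale variance components are typical of national obesity
#' prevalence series: country intercept spread about 0.22, slopes about
#' 0.01-0.02 per year, smooth nonlinear excursions of order 0.1, national
#' study effects of order 0.03, and residual age-by-study noise of 0.05.
#'
#' @param J,L,M,T counts of countries, regions, super-regions and years.
#' @param mid_ages mid-ages of the observed age groups (years).
#' @param population "adult" or "child_adolescent".
#' @param n_categories number of prevalence categories simulated.
#' @param category_labels labels; default "cat1".."catK".
#' @param studies_per_country expected studies per country (scalar).
#' @param kappa named variances of linear components (ac, ar, as_, bc, br, bs).
#' @param lambda RW2 precisions, must be ordered c < r < s < g.
#' @param ag_true,bg_true global intercept and slope (probit scale per
#'   centered year); `ag_true` may be a vector of one intercept per category
#'   (e.g. probit transforms of a calibrated set of category prevalences),
#'   otherwise categories step down by 0.3 from the base value.
#' @param psi_g_true length-5 global spline coefficients.
#' @param sigma_psi length-5 country-level SDs of spline coefficients
#'   (region and super-region levels use half these SDs).
#' @param phi_g_true,sigma_phi adult age-time interaction analogues.
#' @param beta_true length-8 study-design offsets.
#' @param v ordered study random-effect variances (n < s < c).
#' @param tau2 residual age-by-study variance.
#' @param coverage_mix,urban_mix sampling proportions for study labels.
#' @param mean_sample_size mean binomial denominator per age-group row
#'   (lognormal, sd 0.5 on the log scale).
#' @param seed master seed; per-study substreams are derived from it so that
#'   adding studies does not perturb existing ones.
#' @return an object of class "simulation_config".
#' @export
simulation_config <- function(J = 12, L = 4, M = 2, T = 25,
                              mid_ages = c(27.5, 42.5, 57.5),
                              population = "adult",
                              n_categories = 1,
                              category_labels = NULL,
                              studies_per_country = 3,
                              kappa = c(ac = 0.05, ar = 0.05, as_ = 0.02,
                                        bc = 2e-4, br = 1e-4, bs = 5e-5),
                              lambda = c(c = 1e4, r = 3e4, s = 9e4, g = 2.7e5),
                              ag_true = -1.2, bg_true = 0.015,
                              psi_g_true = c(0.02, -5e-4, 0, 0, 0),
                              sigma_psi = c(5e-3, 1e-4, 1e-6, 1e-6, 1e-6),
                              phi_g_true = c(2e-4, 0, 0, 0, 0),
                              sigma_phi = c(2e-4, 1e-6, 1e-8, 1e-8, 1e-8),
                              beta_true = c(-0.05, 1e-3, -0.1, 2e-3,
                                            0.05, -1e-3, 0.08, -2e-3),
                              v = c(n = 1e-3, s = 4e-3, c = 1e-2),
                              tau2 = 2.5e-3,
                              coverage_mix = c(national = 0.6, subnational = 0.25,
                                               community = 0.15),
                              urban_mix = c(both = 0.7, urban = 0.15, rural = 0.15),
                              mean_sample_size = 800,
                              seed = 1L) {
  if (!(lambda[1] < lambda[2] && lambda[2] < lambda[3] && lambda[3] < lambda[4]))
    stop("lambda must be ordered: lambda_c < lambda_r < lambda_s < lambda_g")
  if (!(v[1] < v[2] && v[2] < v[3]))
    stop("v must be ordered: v_n < v_s < v_c")
  if (any(c(kappa, lambda, v, tau2, sigma_psi, sigma_phi) <= 0))
    stop("all variance-type hyperparameters must be positive")
  stopifnot(J >= L, L >= M, M >= 1, T >= 3, length(mid_ages) >= 1)
  if (is.null(category_labels))
    category_labels <- if (n_categories == 1) "obesity" else paste0("cat", seq_len(n_categories))
  structure(as.list(environment()), class = "simulation_config")
}

#' Read a simulation config from a YAML file
#'
#' Scalar and vector keys mirror the arguments of [simulation_config()].
#'
#' @param path YAML file path.
#' @return a simulation_config.
#' @export
simulation_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (nm in c("kappa", "lambda", "v", "coverage_mix", "urban_mix"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(simulation_config, vals)
}

# deterministic per-study seed derived from the master seed
study_substream_seed <- function(seed, j, s) {
  (as.integer(seed) %% 100000L) * 20011L + j * 1009L + s * 7L
}

# draw one constrained RW2 vector (zero mean, zero OLS slope) with precision
# lambda * P, via the spectral pseudoinverse of P
rconstrained_rw2 <- function(pe, lambda) {
  k <- pe$nonnull
  z <- stats::rnorm(length(k)) / sqrt(lambda * pe$values[k])
  u <- as.vector(pe$vectors[, k, drop = FALSE] %*% z)
  project_out_mean_slope(u)
}

# exact projection onto the complement of span{1, t}; also used to verify the
# identifiability constraints
project_out_mean_slope <- function(u, tc = NULL) {
  T <- length(u)
  if (is.null(tc)) tc <- seq_len(T) - (T + 1) / 2
  u <- u - mean(u)
  u - tc * sum(tc * u) / sum(tc * tc)
}

#' Generate a synthetic world
#'
#' Draws one full set of true model parameters from the configured
#' hyperparameters (linear components from zero-mean Gaussians with the kappa
#' variances, RW2 components from the constrained prior at each level, spline
#' coefficients per the age-model hierarchy) and computes the true prevalence
#' surfaces. Regeneration with the same config is bit-identical.
#'
#' @param config a [simulation_config()].
#' @return an object of class "synthetic_world" with elements config,
#'   hierarchy, truth (list of per-category parameter sets), surfaces (from
#'   [simulate_true_surfaces()]) and seed.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  h <- balanced_hierarchy(config$J, config$L, config$M)
  pe <- rw2_penalty_eigen(config$T)
  set.seed(config$seed)
  # per-category global intercepts: either one per category, or a base value
  # stepped down so higher categories are rarer
  ag_vec <- if (length(config$ag_true) == config$n_categories) config$ag_true
            else config$ag_true - 0.3 * (seq_len(config$n_categories) - 1)
  truth <- lapply(seq_len(config$n_categories), function(cat) {
    tr <- list(
      ag = ag_vec[cat], bg = config$bg_true,
      ac = stats::rnorm(config$J, 0, sqrt(config$kappa["ac"])),
      ar = stats::rnorm(config$L, 0, sqrt(config$kappa["ar"])),
      as_ = stats::rnorm(config$M, 0, sqrt(config$kappa["as_"])),
      bc = stats::rnorm(config$J, 0, sqrt(config$kappa["bc"])),
      br = stats::rnorm(config$L, 0, sqrt(config$kappa["br"])),
      bs = stats::rnorm(config$M, 0, sqrt(config$kappa["bs"])),
      uc = t(replicate(config$J, rconstrained_rw2(pe, config$lambda["c"]))),
      ur = t(replicate(config$L, rconstrained_rw2(pe, config$lambda["r"]))),
      us = t(replicate(config$M, rconstrained_rw2(pe, config$lambda["s"]))),
      ug = rconstrained_rw2(pe, config$lambda["g"]),
      psi_g = config$psi_g_true,
      psi_c = matrix(stats::rnorm(5 * config$J, 0, config$sigma_psi), 5, config$J),
      psi_r = matrix(stats::rnorm(5 * config$L, 0, config$sigma_psi / 2), 5, config$L),
      psi_s = matrix(stats::rnorm(5 * config$M, 0, config$sigma_psi / 2), 5, config$M),
      beta = config$beta_true)
    if (config$population == "adult") {
      tr$phi_g <- config$phi_g_true
      tr$phi_c <- matrix(stats::rnorm(5 * config$J, 0, config$sigma_phi), 5, config$J)
      tr$phi_r <- matrix(stats::rnorm(5 * config$L, 0, config$sigma_phi / 2), 5, config$L)
      tr$phi_s <- matrix(stats::rnorm(5 * config$M, 0, config$sigma_phi / 2), 5, config$M)
    }
    tr
  })
  # country-year urbanization covariate, constant in time per country
  curb <- stats::runif(config$J, 0.2, 0.9)
  world <- structure(list(config = config, hierarchy = h, truth = truth,
                          urbanization = curb, seed = config$seed),
                     class = "synthetic_world")
  world$surfaces <- simulate_true_surfaces(world)
  world
}

# true latent country-year-age mean for one category's parameter set
true_latent_mean <- function(tr, h, T, mid_ages, knots, age_center, population) {
  tc <- seq_len(T) - (T + 1) / 2
  B <- age_spline_basis(mid_ages, knots, age_center)       # ages x 5
  a <- tr$ac + tr$ar[h$region_of] + tr$as_[h$sregion_of_country] + tr$ag
  b <- tr$bc + tr$br[h$region_of] + tr$bs[h$sregion_of_country] + tr$bg
  U <- tr$uc + tr$ur[h$region_of, , drop = FALSE] +
    tr$us[h$sregion_of_country, , drop = FALSE] +
    matrix(tr$ug, h$J, T, byrow = TRUE)
  psi <- tr$psi_c + tr$psi_r[, h$region_of, drop = FALSE] +
    tr$psi_s[, h$sregion_of_country, drop = FALSE] + tr$psi_g
  phi <- if (population == "adult")
    tr$phi_c + tr$phi_r[, h$region_of, drop = FALSE] +
      tr$phi_s[, h$sregion_of_country, drop = FALSE] + tr$phi_g else NULL
  out <- array(0, c(h$J, T, length(mid_ages)))
  for (hh in seq_along(mid_ages)) {
    agej <- as.vector(B[hh, , drop = FALSE] %*% psi)       # length J
    out[, , hh] <- a + outer(b, tc) + U + agej
    if (!is.null(phi)) {
      agesl <- as.vector(B[hh, , drop = FALSE] %*% phi)
      out[, , hh] <- out[, , hh] + outer(agesl, tc)
    }
  }
  out
}

#' True prevalence surfaces of a synthetic world
#'
#' Prevalence is the standard-normal CDF of the true latent mean
#' (a_j + b_j t + u_{j,t} + age term) per category; with more than one
#' category the per-cell values are renormalized to sum to one, mirroring the
#' per-category fitting followed by rescaling used for inference.
#'
#' @param world a [generate_world()] result.
#' @return array [J, T, n_ages, n_categories] of true prevalences, with the
#'   raw (pre-rescale) surface in attribute "raw".
#' @export
simulate_true_surfaces <- function(world) {
  cf <- world$config
  knots <- if (cf$population == "adult") c(45, 60) else c(10, 15)
  center <- if (cf$population == "adult") 50 else 12
  raw <- array(0, c(cf$J, cf$T, length(cf$mid_ages), cf$n_categories))
  for (cat in seq_len(cf$n_categories)) {
    m <- true_latent_mean(world$truth[[cat]], world$hierarchy, cf$T,
                          cf$mid_ages, knots, center, cf$population)
    raw[, , , cat] <- stats::pnorm(m)
  }
  out <- raw
  if (cf$n_categories > 1) {
    tot <- apply(raw, 1:3, sum)
    for (cat in seq_len(cf$n_categories)) out[, , , cat] <- raw[, , , cat] / tot
  }
  attr(out, "raw") <- raw
  dimnames(out) <- list(NULL, NULL, NULL, cf$category_labels)
  out
}

#' Simulate an observation table from a synthetic world
#'
#' Assigns each synthetic study a year, coverage and urban-scope label, a
#' study random effect with coverage-dependent variance and a design offset
#' X beta on the probit scale, then draws the latent alpha with residual
#' variance tau2 and binomial counts per age-group row. Each study uses its
#' own seed substream derived from the master seed.
#'
#' @param world a [generate_world()] result.
#' @param sex label stored on the rows (analyses are sex-specific).
#' @return data frame of observation rows; the per-study truth (year, e_i,
#'   labels) is attached as attribute "study_truth".
#' @export
simulate_observations <- function(world, sex = "female") {
  cf <- world$config
  h <- world$hierarchy
  knots <- if (cf$population == "adult") c(45, 60) else c(10, 15)
  center <- if (cf$population == "adult") 50 else 12
  B <- age_spline_basis(cf$mid_ages, knots, center)
  rows <- list(); st_truth <- list()
  for (j in seq_len(cf$J)) {
    for (s in seq_len(cf$studies_per_country)) {
      set.seed(study_substream_seed(cf$seed, j, s))
      year <- sample.int(cf$T, 1)
      tcv <- year - (cf$T + 1) / 2
      coverage <- sample(names(cf$coverage_mix), 1, prob = cf$coverage_mix)
      urban <- sample(names(cf$urban_mix), 1, prob = cf$urban_mix)
      curb <- world$urbanization[j]
      x <- study_design_vector(coverage, urban, tcv, curb)
      covi <- match(coverage, c("national", "subnational", "community"))
      ei <- stats::rnorm(1, 0, sqrt(cf$v[covi]))
      nrow_sizes <- pmax(20, round(stats::rlnorm(length(cf$mid_ages),
                                                 log(cf$mean_sample_size), 0.5)))
      sid <- sprintf("study_%02d_%02d", j, s)
      for (cat in seq_len(cf$n_categories)) {
        tr <- world$truth[[cat]]
        psi_j <- tr$psi_c[, j] + tr$psi_r[, h$region_of[j]] +
          tr$psi_s[, h$sregion_of_country[j]] + tr$psi_g
        agev <- as.vector(B %*% psi_j)
        if (cf$population == "adult") {
          phi_j <- tr$phi_c[, j] + tr$phi_r[, h$region_of[j]] +
            tr$phi_s[, h$sregion_of_country[j]] + tr$phi_g
          agev <- agev + as.vector(B %*% phi_j) * tcv
        }
        aj <- tr$ac[j] + tr$ar[h$region_of[j]] + tr$as_[h$sregion_of_country[j]] + tr$ag
        bj <- tr$bc[j] + tr$br[h$region_of[j]] + tr$bs[h$sregion_of_country[j]] + tr$bg
        uj <- tr$uc[j, year] + tr$ur[h$region_of[j], year] +
          tr$us[h$sregion_of_country[j], year] + tr$ug[year]
        mu <- aj + bj * tcv + uj + agev + sum(x * tr$beta) + ei
        alpha <- stats::rnorm(length(mu), mu, sqrt(cf$tau2))
        y <- stats::rbinom(length(alpha), nrow_sizes, stats::pnorm(alpha))
        rows[[length(rows) + 1L]] <- data.frame(
          study_id = sid, country = j, year = year, sex = sex,
          mid_age = cf$mid_ages, category = cf$category_labels[cat],
          y = y, n = nrow_sizes, coverage = coverage, urban_scope = urban,
          country_urbanization = curb)
      }
      st_truth[[length(st_truth) + 1L]] <- data.frame(
        study_id = sid, country = j, year = year, coverage = coverage,
        urban_scope = urban, e = ei)
    }
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  attr(obs, "study_truth") <- do.call(rbind, st_truth)
  obs
}
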