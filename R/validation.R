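#' Hold-out split for external predictive validation
#'
#' Two designs. Test 1 ("test1_countries") withholds all rows of a fraction
#' of countries with data, sampled within data-richness strata (data-poor /
#' average / data-rich, by study count). Test 2 ("test2_sources") samples the
#' same fraction of countries and, per sampled country, withholds either a
#' random one-third of its studies or all studies dated in a recent window
#' (chosen at random per country), probing gap-filling and extrapolation
#' beyond the last data year respectively.
#'
#' @param obs observation table with columns study_id, country, year.
#' @param design "test1_countries" or "test2_sources".
#' @param fraction fraction of countries sampled (default 0.10).
#' @param replicate replicate id (each replicate gets a disjoint seed stream).
#' @param seed master seed.
#' @param rich_thresholds study-count cutpoints c(poor_max, avg_max): <=
#'   poor_max studies is data-poor, <= avg_max average, else data-rich.
#' @param recent_window years (on the model's 1..T scale) defining "recent"
#'   for test 2; default the top third of observed years.
#' @return object of class "holdout_split": `withheld` (row indices),
#'   `countries`, `strata` (country stratum labels), `design`, `replicate`.
#' @export
make_holdout_split <- function(obs, design = c("test1_countries", "test2_sources"),
                               fraction = 0.10, replicate = 1L, seed = 1L,
                               rich_thresholds = c(2, 6),
                               recent_window = NULL) {
  design <- match.arg(design)
  set.seed(derive_seed(seed, 10000L + replicate))
  studies_by_country <- tapply(obs$study_id, obs$country,
                               function(x) length(unique(x)))
  countries <- as.integer(names(studies_by_country))
  stratum <- cut(as.vector(studies_by_country),
                 breaks = c(-Inf, rich_thresholds, Inf),
                 labels = c("data_poor", "average", "data_rich"))
  n_hold <- max(1L, round(fraction * length(countries)))
  if (n_hold < 1L) stop("fraction yields zero countries to withhold")
  # allocate the held-out countries proportionally across strata
  per_str <- table(stratum)
  alloc <- pmax(0L, round(n_hold * per_str / sum(per_str)))
  while (sum(alloc) < n_hold) alloc[which.max(per_str - alloc)] <- alloc[which.max(per_str - alloc)] + 1L
  while (sum(alloc) > n_hold) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  sel <- integer(0)
  for (s in names(alloc)) {
    pool <- countries[stratum == s]
    if (length(pool) && alloc[[s]] > 0)
      sel <- c(sel, sample(pool, min(alloc[[s]], length(pool))))
  }
  if (!length(sel)) sel <- sample(countries, n_hold)

  if (design == "test1_countries") {
    withheld <- which(obs$country %in% sel)
    mode <- rep("all", length(sel))
  } else {
    if (is.null(recent_window)) {
      yrs <- sort(unique(obs$year))
      recent_window <- yrs[yrs >= stats::quantile(yrs, 2 / 3, type = 1)]
    }
    withheld <- integer(0)
    mode <- character(length(sel))
    for (i in seq_along(sel)) {
      j <- sel[i]
      rows_j <- which(obs$country == j)
      studies_j <- unique(obs$study_id[rows_j])
      mode[i] <- sample(c("third", "recent"), 1)
      if (mode[i] == "recent" &&
          any(obs$year[rows_j] %in% recent_window) &&
          !all(obs$year[rows_j] %in% recent_window)) {
        withheld <- c(withheld, rows_j[obs$year[rows_j] %in% recent_window])
      } else {
        mode[i] <- "third"
        ns <- max(1L, round(length(studies_j) / 3))
        out_st <- sample(studies_j, ns)
        withheld <- c(withheld, rows_j[obs$study_id[rows_j] %in% out_st])
      }
    }
  }
  structure(list(withheld = sort(unique(withheld)), countries = sel,
                 strata = stats::setNames(as.character(stratum), countries),
                 mode = mode, design = design, replicate = replicate,
                 seed = seed),
            class = "holdout_split")
}

#' Error metrics for held-out observations
#'
#' Pairs estimates with withheld observations by exact key and reports, per
#' data-richness stratum and overall: the median error (estimate minus
#' observation, percentage points), the median absolute error, and the
#' fraction of withheld values inside the supplied 95% intervals (coverage).
#'
#' @param estimates data frame with key columns (country, year, study_id,
#'   mid_age), `est`, `lower`, `upper` -- prevalences in [0,1].
#' @param observed data frame with the same keys and column `obs` (prevalence
#'   in [0,1]), plus optional `stratum`.
#' @return object of class "error_report": data frame with rows per stratum
#'   and "overall" (median_error_pp, median_abs_error_pp, coverage, n).
#' @export
compute_error_metrics <- function(estimates, observed) {
  keys <- intersect(c("country", "year", "study_id", "mid_age"),
                    intersect(names(estimates), names(observed)))
  if (!length(keys)) stop("no shared key columns between estimates and observations")
  kest <- do.call(paste, c(estimates[keys], sep = "\r"))
  kobs <- do.call(paste, c(observed[keys], sep = "\r"))
  idx <- match(kobs, kest)
  if (anyNA(idx))
    stop("withheld rows without matching estimates: ",
         paste(utils::head(kobs[is.na(idx)], 5), collapse = "; "))
  err <- 100 * (estimates$est[idx] - observed$obs)
  cov <- observed$obs >= estimates$lower[idx] & observed$obs <= estimates$upper[idx]
  stratum <- observed$stratum %||% rep("overall", nrow(observed))
  summarize <- function(sel, label) data.frame(
    stratum = label, median_error_pp = stats::median(err[sel]),
    median_abs_error_pp = stats::median(abs(err[sel])),
    coverage = mean(cov[sel]), n = sum(sel))
  out <- do.call(rbind, lapply(unique(stratum), function(s)
    summarize(stratum == s, s)))
  if (!identical(unique(stratum), "overall"))
    out <- rbind(out, summarize(rep(TRUE, length(err)), "overall"))
  class(out) <- c("error_report", "data.frame")
  out
}

#' Posterior predictive estimates for held-out study rows
#'
#' For each withheld row, forms the posterior predictive distribution of a
#' new study observation at that row's country, year and age: the country-
#' year-age latent mean plus a fresh study effect (variance by the row's
#' coverage class), residual age-by-study noise tau2, and binomial sampling
#' with the row's denominator. Intervals against which held-out data are
#' compared must carry these noise sources; intervals for the latent country
#' prevalence alone would be too narrow.
#'
#' @param fit a [fit_prevalence_model()] result.
#' @param rows withheld observation rows (data frame).
#' @param include_binomial include the binomial sampling layer (default TRUE).
#' @return data frame: keys, est (predictive mean), lower, upper (2.5-97.5th
#'   predictive percentiles).
#' @export
predict_heldout <- function(fit, rows, include_binomial = TRUE) {
  draws <- fit$combined
  nd <- nrow(draws$a)
  T <- fit$T
  B <- age_spline_basis(rows$mid_age, fit$knots, fit$age_center)
  vdraws <- exp(draws$hyper[, paste0("log_v_", c("n", "s", "c")), drop = FALSE])
  tau2d <- exp(draws$hyper[, "log_tau2"])
  out <- rows[c("study_id", "country", "year", "mid_age")]
  out$est <- NA_real_; out$lower <- NA_real_; out$upper <- NA_real_
  covc <- match(rows$coverage, c("national", "subnational", "community"))
  for (i in seq_len(nrow(rows))) {
    j <- rows$country[i]; t <- rows$year[i]; tc <- t - fit$t_center
    m <- draws$a[, j] + draws$b[, j] * tc + draws$u[, (j - 1) * T + t] +
      as.vector(draws$psi[, (j - 1) * 5 + 1:5, drop = FALSE] %*% B[i, ])
    if (!is.null(draws$phi))
      m <- m + as.vector(draws$phi[, (j - 1) * 5 + 1:5, drop = FALSE] %*% B[i, ]) * tc
    estar <- stats::rnorm(nd, 0, sqrt(vdraws[, covc[i]]))
    astar <- stats::rnorm(nd, m + estar, sqrt(tau2d))
    p <- stats::pnorm(astar)
    pred <- if (include_binomial) stats::rbinom(nd, round(rows$n[i]), p) / round(rows$n[i]) else p
    q <- stats::quantile(pred, c(0.025, 0.975), type = 7, names = FALSE)
    out$est[i] <- mean(pred); out$lower[i] <- q[1]; out$upper[i] <- q[2]
  }
  out
}

#' Self-consistency validation on model-generated data
#'
#' Generates a synthetic world, simulates observations, withholds data per
#' the chosen design, fits the model to the retained rows, and scores the
#' withheld rows with [predict_heldout()] and [compute_error_metrics()].
#'
#' @param config a [simulation_config()].
#' @param sampler a [sampler_config()].
#' @param design,fraction,replicate,seed passed to [make_holdout_split()].
#' @param pilot run the pilot initialization phase (default FALSE at reduced
#'   scale).
#' @return list: `report` (error_report), `split`, `fit`.
#' @export
validate_self_consistency <- function(config, sampler,
                                      design = "test2_sources",
                                      fraction = 0.10, replicate = 1L,
                                      seed = config$seed, pilot = FALSE) {
  world <- generate_world(config)
  obs <- simulate_observations(world)
  split <- make_holdout_split(obs, design, fraction, replicate, seed)
  retained <- obs[-split$withheld, , drop = FALSE]
  withheld <- obs[split$withheld, , drop = FALSE]
  if (!nrow(withheld)) stop("holdout produced no withheld rows")
  fit <- fit_prevalence_model(retained, world$hierarchy, config$T,
                              population = config$population,
                              config = sampler, pilot = pilot)
  est <- predict_heldout(fit, withheld)
  observed <- withheld[c("study_id", "country", "year", "mid_age")]
  observed$obs <- withheld$y / withheld$n
  observed$stratum <- split$strata[as.character(withheld$country)]
  report <- compute_error_metrics(est, observed)
  list(report = report, split = split, fit = fit)
}
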