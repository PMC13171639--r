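#' Posterior prevalence draws for country-year-age cells
#'
#' Combines the posterior draws of the composite a, b, u and spline terms
#' into country-year-age latent means -- with the study-design offsets beta
#' and study effects e set to zero, since study-implementation terms are not
#' relevant for country-level inference -- and transforms by the
#' standard-normal CDF. One category per call.
#'
#' @param fit a [fit_prevalence_model()] result.
#' @param mid_ages mid-ages (years) of the prediction age grid.
#' @param years integer years (1..T) to predict; all by default.
#' @param draws draw set; defaults to the fit's combined thinned draws.
#' @return array [draws, country, year, age] of prevalences in (0,1), with
#'   dimnames on the year axis.
#' @export
predict_prevalence_draws <- function(fit, mid_ages, years = NULL, draws = NULL) {
  if (is.null(draws)) draws <- fit$combined
  if (is.null(years)) years <- seq_len(fit$T)
  if (any(years < 1 | years > fit$T)) stop("requested year outside 1..T")
  J <- fit$J; T <- fit$T
  nd <- nrow(draws$a); H <- length(mid_ages)
  B <- age_spline_basis(mid_ages, fit$knots, fit$age_center)  # H x 5
  out <- array(NA_real_, c(nd, J, length(years), H),
               dimnames = list(NULL, NULL, years, NULL))
  for (j in seq_len(J)) {
    psi_j <- draws$psi[, (j - 1) * 5 + 1:5, drop = FALSE]     # nd x 5
    agemat <- psi_j %*% t(B)                                  # nd x H
    phimat <- if (!is.null(draws$phi))
      draws$phi[, (j - 1) * 5 + 1:5, drop = FALSE] %*% t(B) else NULL
    for (ti in seq_along(years)) {
      t <- years[ti]
      tc <- t - fit$t_center
      m <- draws$a[, j] + draws$b[, j] * tc + draws$u[, (j - 1) * T + t]
      mm <- m + agemat
      if (!is.null(phimat)) mm <- mm + phimat * tc
      out[, j, ti, ] <- stats::pnorm(mm)
    }
  }
  out
}

#' Rescale category surfaces and extract obesity
#'
#' Categories are fitted independently, so their estimated prevalences need
#' not sum to one; per draw-country-year-age cell, each category is divided
#' by the category sum. Obesity is the sum of the rescaled bands at or above
#' 30 kg/m^2 for adults (or the > +2 z-score band for children).
#'
#' @param surfaces 5-d array [draws, country, year, age, category] with
#'   category dimnames, or a named list of 4-d arrays.
#' @param obesity_categories labels of the categories summed into obesity.
#' @return list: `rescaled` (same shape), `obesity` [draws, country, year,
#'   age], `scaling` (per-cell rescaling factor, same shape as obesity).
#' @export
rescale_and_obesity <- function(surfaces,
                                obesity_categories = c("30to35", "35to40", "gte40")) {
  if (is.list(surfaces)) {
    labs <- names(surfaces)
    dims <- dim(surfaces[[1]])
    arr <- array(NA_real_, c(dims, length(surfaces)),
                 dimnames = c(dimnames(surfaces[[1]]) %||% rep(list(NULL), 4),
                              list(labs)))
    for (i in seq_along(surfaces)) arr[, , , , i] <- surfaces[[i]]
    surfaces <- arr
  }
  labs <- dimnames(surfaces)[[5]]
  if (is.null(labs)) stop("category dimension must be labelled")
  tot <- apply(surfaces, 1:4, sum)
  if (any(tot <= 0)) stop("category sum is not positive in at least one cell")
  scaling <- 1 / tot
  rescaled <- surfaces
  for (i in seq_along(labs)) rescaled[, , , , i] <- surfaces[, , , , i] * scaling
  ob_labs <- intersect(obesity_categories, labs)
  if (!length(ob_labs)) stop("no obesity categories present in the surface")
  obesity <- apply(rescaled[, , , , ob_labs, drop = FALSE], 1:4, sum)
  list(rescaled = rescaled, obesity = obesity, scaling = scaling)
}

#' Standard population age weights
#'
#' @param age_groups labels of the age bands.
#' @param weights nonnegative weights; normalized to sum to one.
#' @return data frame (age_group, weight) of class "standard_population".
#' @export
standard_population <- function(age_groups, weights) {
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be nonnegative, not all zero")
  out <- data.frame(age_group = as.character(age_groups),
                    weight = weights / sum(weights))
  class(out) <- c("standard_population", "data.frame")
  out
}

#' WHO-style world standard population
#'
#' The conventional world standard population age weights in 5-year bands
#' (percentages of a standard world population), bundled as the default for
#' age standardization; restrict with `min_age`/`max_age` and the weights are
#' renormalized over the retained bands.
#'
#' @param min_age,max_age band filter (band lower edges).
#' @return a [standard_population()].
#' @export
who_standard_population <- function(min_age = 0, max_age = Inf) {
  lo <- seq(0, 85, 5)
  w <- c(8.86, 8.69, 8.60, 8.47, 8.22, 7.93, 7.61, 7.15, 6.59, 6.04,
         5.37, 4.55, 3.72, 2.96, 2.21, 1.52, 0.91, 0.63)
  keep <- lo >= min_age & lo <= max_age
  lab <- ifelse(lo == 85, "85plus", sprintf("%d-%d", lo, lo + 4))
  standard_population(lab[keep], w[keep])
}

#' Age-standardized prevalence series
#'
#' Weighted mean of age-specific prevalences using a fixed standard age
#' distribution, per draw, country and year.
#'
#' @param surface array [draws, country, year, age].
#' @param std a [standard_population()]; its rows must match the age
#'   dimension (by position, or by dimnames when the age axis is labelled).
#' @return array [draws, country, year].
#' @export
age_standardize <- function(surface, std) {
  H <- dim(surface)[4]
  ages <- dimnames(surface)[[4]]
  if (!is.null(ages)) {
    idx <- match(ages, std$age_group)
    if (anyNA(idx))
      stop("missing standard-population weight for age band(s): ",
           paste(ages[is.na(idx)], collapse = ", "))
    w <- std$weight[idx]
  } else {
    if (nrow(std) != H) stop("standard population does not cover the age grid")
    w <- std$weight
  }
  w <- w / sum(w)
  out <- array(0, dim(surface)[1:3], dimnames = dimnames(surface)[1:3])
  for (hh in seq_len(H)) {
    slab <- surface[, , , hh, drop = FALSE]
    dim(slab) <- dim(surface)[1:3]
    out <- out + slab * w[hh]
  }
  out
}

#' Year-on-year velocity of age-standardized prevalence
#'
#' Signed change in age-standardized prevalence between consecutive years, in
#' percentage points per year, labelled by the terminal year (the change from
#' year 23 to 24 is the velocity in year 24). Negative velocities are
#' decreases. Per draw, the velocities telescope: they sum to the difference
#' between the last and first year.
#'
#' @param std_series array [draws, country, year] of prevalences in [0,1],
#'   with year dimnames, or a draws x years matrix for one country.
#' @return array [draws, country, years-1] in percentage points, terminal
#'   year as dimnames.
#' @export
velocity_series <- function(std_series) {
  if (length(dim(std_series)) == 2)
    std_series <- array(std_series, c(nrow(std_series), 1, ncol(std_series)),
                        dimnames = list(NULL, NULL, colnames(std_series)))
  ny <- dim(std_series)[3]
  if (ny < 2) stop("velocity needs at least 2 years")
  yl <- dimnames(std_series)[[3]]
  vel <- 100 * (std_series[, , 2:ny, drop = FALSE] -
                  std_series[, , seq_len(ny - 1), drop = FALSE])
  dimnames(vel)[[3]] <- if (!is.null(yl)) yl[2:ny] else NULL
  vel
}

#' Posterior summaries of a draw vector
#'
#' Mean, 2.5-97.5th percentile interval (order statistics, type-7
#' interpolation) and the posterior probability of positivity (fraction of
#' draws strictly greater than zero; exact zeros count as not positive).
#'
#' @param x numeric vector of posterior draws.
#' @param interval tail probabilities of the credible interval.
#' @return named list: mean, lower, upper, pp_positive.
#' @export
posterior_summaries <- function(x, interval = c(0.025, 0.975)) {
  if (!length(x)) stop("no draws supplied")
  q <- stats::quantile(x, probs = interval, type = 7, names = FALSE)
  list(mean = mean(x), lower = q[1], upper = q[2],
       pp_positive = mean(x > 0))
}

#' Tidy summary table of a prevalence surface
#'
#' @param surface array [draws, country, year, age].
#' @param sex,category metadata columns added to the output.
#' @return data frame (sex, country, year, age_group, category, mean, l95,
#'   u95) ready for CSV export.
#' @export
prevalence_summary_table <- function(surface, sex = NA, category = NA) {
  dims <- dim(surface)
  grid <- expand.grid(country = seq_len(dims[2]), year = seq_len(dims[3]),
                      age = seq_len(dims[4]))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- posterior_summaries(surface[, grid$country[i], grid$year[i], grid$age[i]])
    data.frame(sex = sex, country = grid$country[i], year = grid$year[i],
               age_group = grid$age[i], category = category,
               mean = s$mean, l95 = s$lower, u95 = s$upper)
  })
  do.call(rbind, rows)
}
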