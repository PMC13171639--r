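#' Cubic spline basis for the age model
#'
#' Evaluates the 5-dimensional truncated power basis used for the age pattern
#' of probit-transformed prevalence:
#' \eqn{(z_c, z_c^2, z_c^3, (z-k_1)_+^3, (z-k_2)_+^3)}, where
#' \eqn{z_c = z - center}. Knots default to (45, 60) years for adults and
#' (10, 15) for children and adolescents. Centering the age variable reduces
#' dependence among the polynomial coefficients; the truncated terms are
#' anchored at the uncentred knots so the function and its first and second
#' derivatives are continuous at the knots.
#'
#' @param z numeric vector of mid-ages in years.
#' @param knots numeric length-2 vector (k1, k2), k1 < k2.
#' @param center age-centering constant in years (0 = no centering).
#' @return A length(z) x 5 numeric matrix.
#' @examples
#' age_spline_basis(70, knots = c(45, 60), center = 0)  # last two: 15625, 1000
#' @export
age_spline_basis <- function(z, knots = c(45, 60), center = 0) {
  stopifnot(length(knots) == 2L, knots[1] < knots[2], is.finite(z))
  zc <- z - center
  cbind(zc, zc^2, zc^3,
        pmax(z - knots[1], 0)^3,
        pmax(z - knots[2], 0)^3,
        deparse.level = 0)
}

#' Study-design fixed-effect vector
#'
#' Builds the 8-entry design row multiplying the study-level offsets beta:
#' subnational intercept and time slope, community intercept and slope,
#' rural-only intercept and slope weighted by the proportion of the country's
#' population living in urban areas, and urban-only intercept and slope
#' weighted by one minus that proportion. Nationally representative studies
#' covering both urban and rural areas get an all-zero row, as do urban-only
#' studies in fully urban countries and rural-only studies in fully rural
#' countries.
#'
#' @param coverage one of "national", "subnational", "community".
#' @param urban_scope one of "both", "urban", "rural".
#' @param t study time (on whatever scale the model uses; the fitter passes
#'   centered time).
#' @param country_urbanization proportion of the country's population living
#'   in urban areas in the study year, in [0, 1].
#' @return numeric vector of length 8.
#' @examples
#' study_design_vector("subnational", "rural", t = 3, country_urbanization = 0.4)
#' @export
study_design_vector <- function(coverage, urban_scope, t, country_urbanization) {
  coverage <- match.arg(coverage, c("national", "subnational", "community"))
  urban_scope <- match.arg(urban_scope, c("both", "urban", "rural"))
  stopifnot(is.finite(t), is.finite(country_urbanization),
            country_urbanization >= 0, country_urbanization <= 1)
  sub <- as.numeric(coverage == "subnational")
  com <- as.numeric(coverage == "community")
  rur <- as.numeric(urban_scope == "rural") * country_urbanization
  urb <- as.numeric(urban_scope == "urban") * (1 - country_urbanization)
  c(sub, sub * t, com, com * t, rur, rur * t, urb, urb * t)
}
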