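#' BMI category scheme
#'
#' Defines the category bands used throughout the pipeline. Adults are
#' classified into seven half-open BMI bands with cut-points at 18.5, 20, 25,
#' 30, 35 and 40 kg/m^2 (each band [lower, upper)). Children and adolescents
#' are classified into five bands of the BMI-for-age z-score relative to a
#' growth reference: z < -2, -2 <= z < -1, -1 <= z <= 1, 1 < z <= 2, and
#' z > 2 (the obesity band is strictly above +2).
#'
#' @param population "adult" or "child_adolescent".
#' @param reference for the child scheme, a growth-reference data frame with
#'   columns sex, age, L, M, S (see [synthetic_growth_reference()]).
#' @return An object of class "category_scheme" with elements population,
#'   labels, and (adult) cutpoints or (child) reference.
#' @export
bmi_category_scheme <- function(population = c("adult", "child_adolescent"),
                                reference = NULL) {
  population <- match.arg(population)
  if (population == "adult") {
    cut <- c(18.5, 20, 25, 30, 35, 40)
    labels <- c("lt18_5", "18_5to20", "20to25", "25to30", "30to35", "35to40", "gte40")
    structure(list(population = population, cutpoints = cut, labels = labels),
              class = "category_scheme")
  } else {
    if (is.null(reference))
      stop("child_adolescent scheme requires a growth reference table")
    stopifnot(all(c("sex", "age", "L", "M", "S") %in% names(reference)))
    labels <- c("zlt_m2", "zm2_m1", "zm1_1", "z1_2", "zgt2")
    structure(list(population = population, reference = reference, labels = labels),
              class = "category_scheme")
  }
}

#' BMI-for-age z-score from an LMS growth reference
#'
#' Box-Cox (LMS) transform: \eqn{z = ((bmi/M)^L - 1) / (L S)} for L != 0 and
#' \eqn{z = log(bmi/M)/S} for L = 0.
#'
#' @param bmi BMI in kg/m^2.
#' @param age age in years (matched exactly against the reference rows).
#' @param sex "female" or "male".
#' @param reference data frame with columns sex, age, L, M, S.
#' @return numeric z-score(s).
#' @export
lms_zscore <- function(bmi, age, sex, reference) {
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(bmi, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  key <- paste(reference$sex, reference$age)
  idx <- match(paste(sex, age), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("no growth-reference row for (age = %s, sex = %s)",
                 age[bad], sex[bad]))
  }
  L <- reference$L[idx]; M <- reference$M[idx]; S <- reference$S[idx]
  ifelse(abs(L) < 1e-12, log(bmi / M) / S, ((bmi / M)^L - 1) / (L * S))
}

#' Assign a BMI category
#'
#' Maps a BMI value to exactly one category of the scheme. Adult bands are
#' half-open [lower, upper): a BMI of exactly 18.5 falls in the 18.5-20 band,
#' 30.0 in the 30-35 band. Child bands are applied to the LMS z-score; a
#' z-score of exactly +2 belongs to the (1, 2] band, obesity requires z > 2.
#'
#' @param age age in years (used for the child reference lookup; ignored for
#'   adults).
#' @param sex "female" or "male" (ignored for adults).
#' @param bmi BMI in kg/m^2, finite.
#' @param scheme a [bmi_category_scheme()].
#' @return character vector of category labels.
#' @export
assign_bmi_category <- function(age, sex, bmi, scheme) {
  if (any(!is.finite(bmi))) stop("bmi must be finite")
  if (scheme$population == "adult") {
    idx <- findInterval(bmi, scheme$cutpoints) + 1L  # [lower, upper) bands
    scheme$labels[idx]
  } else {
    z <- lms_zscore(bmi, age, sex, scheme$reference)
    # round to 9 decimals so BMI values that sit exactly on a z-score
    # boundary are classified deterministically despite the LMS round trip
    z <- round(z, 9)
    # bands: z < -2 | [-2,-1) | [-1,1] | (1,2] | > 2
    idx <- ifelse(z < -2, 1L,
           ifelse(z < -1, 2L,
           ifelse(z <= 1, 3L,
           ifelse(z <= 2, 4L, 5L))))
    scheme$labels[idx]
  }
}

#' Synthetic LMS growth reference
#'
#' A smooth synthetic growth-reference table (BMI-for-age L, M, S by sex and
#' single year of age 5-19) shipped so the child/adolescent category scheme is
#' testable without external downloads. It mimics the broad shape of published
#' BMI-for-age references (median rising from about 15.3 to 22 kg/m^2 between
#' ages 5 and 19, mild skewness, coefficient of variation around 0.1) but is
#' not any official reference. The same table ships as a CSV at
#' `system.file("extdata", "synthetic_growth_reference.csv", package =
#' "bmitrend")`, illustrating the (sex, age, L, M, S) reference format.
#'
#' @param ages integer vector of ages in years.
#' @return data frame with columns sex, age, L, M, S.
#' @export
synthetic_growth_reference <- function(ages = 5:19) {
  grid <- expand.grid(age = ages, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  a <- grid$age
  off <- ifelse(grid$sex == "male", -0.1, 0)
  data.frame(sex = grid$sex, age = a,
             L = -1.6 + 0.02 * (a - 5),
             M = 15.3 + 0.48 * (a - 5) + off,
             S = 0.09 + 0.002 * (a - 5))
}
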