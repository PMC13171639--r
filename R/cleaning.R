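#' Cleaning rules for individual-level records
#'
#' Admissible ranges for height, weight and BMI by age band. The defaults are
#' the predefined plausibility ranges used for measured anthropometry:
#' height 60-180 cm (< 10 years), 80-200 cm (10-14 years), 100-250 cm
#' (15 years or older); weight 5-90, 8-150, 12-300 kg; BMI 6-40, 8-60,
#' 10-80 kg/m^2 for the same bands. Records of pregnant participants are
#' excluded, as are participants younger than 18 whose age is not reported in
#' single years. Band membership at exactly 10 and 15 completed years goes to
#' the older band.
#'
#' @param height,weight,bmi 3 x 2 numeric matrices of closed-interval limits
#'   (rows: age bands <10, 10-14, >=15; columns: lower, upper).
#' @param exclude_pregnant logical.
#' @param require_single_year_age_under18 logical.
#' @return An object of class "cleaning_rules".
#' @export
cleaning_rules <- function(height = rbind(c(60, 180), c(80, 200), c(100, 250)),
                           weight = rbind(c(5, 90), c(8, 150), c(12, 300)),
                           bmi = rbind(c(6, 40), c(8, 60), c(10, 80)),
                           exclude_pregnant = TRUE,
                           require_single_year_age_under18 = TRUE) {
  for (m in list(height, weight, bmi)) {
    stopifnot(is.matrix(m), nrow(m) == 3L, ncol(m) == 2L, all(m[, 1] < m[, 2]))
  }
  structure(list(height = height, weight = weight, bmi = bmi,
                 exclude_pregnant = exclude_pregnant,
                 require_single_year_age_under18 = require_single_year_age_under18),
            class = "cleaning_rules")
}

# age band index: 1 = <10, 2 = 10-14, 3 = >=15 (completed years)
age_band_index <- function(age) ifelse(age < 10, 1L, ifelse(age < 15, 2L, 3L))

#' Apply cleaning rules to participant records
#'
#' Excludes records that are (a) flagged pregnant, (b) under 18 without
#' single-year age, or (c) outside the age-band plausibility range for any
#' recorded measure (height, weight or BMI). BMI is derived as
#' weight / (height/100)^2 when absent. A record with several violations is
#' counted once, under the first reason in the order pregnancy, age
#' reporting, height, weight, BMI. The operation is idempotent: reapplying the
#' rules to the retained records excludes nothing.
#'
#' @param records data frame with columns study_id, sex ("female"/"male"),
#'   age (years), and at least one of height (cm), weight (kg), bmi (kg/m^2);
#'   optional columns pregnant (logical), single_year_age (logical),
#'   survey_weight, stratum, cluster.
#' @param rules a [cleaning_rules()] object.
#' @return list with elements `retained` (data frame), `excluded` (data frame
#'   with a `reason` column) and `log` (named integer vector of exclusion
#'   counts by reason).
#' @export
apply_cleaning_rules <- function(records, rules = cleaning_rules()) {
  stopifnot(is.data.frame(records), "age" %in% names(records))
  if (!any(c("height", "weight", "bmi") %in% names(records)))
    stop("records must have at least one of height, weight, bmi")
  n <- nrow(records)
  if (any(!records$sex %in% c("female", "male")))
    stop("unknown sex value; expected 'female' or 'male' [err_sex]")
  for (v in intersect(c("height", "weight", "bmi", "age"), names(records))) {
    if (any(records[[v]] < 0, na.rm = TRUE))
      stop(sprintf("negative %s values are not valid measurements [err_negative]", v))
  }
  if (any(records$age < 5, na.rm = TRUE))
    stop("records below age 5 are outside the modelled population [err_age]")

  height <- if ("height" %in% names(records)) records$height else rep(NA_real_, n)
  weight <- if ("weight" %in% names(records)) records$weight else rep(NA_real_, n)
  bmi <- if ("bmi" %in% names(records)) records$bmi else rep(NA_real_, n)
  derive <- is.na(bmi) & !is.na(height) & !is.na(weight)
  bmi[derive] <- weight[derive] / (height[derive] / 100)^2
  pregnant <- if ("pregnant" %in% names(records)) isTRUE_vec(records$pregnant) else rep(FALSE, n)
  single <- if ("single_year_age" %in% names(records)) isTRUE_vec(records$single_year_age) else rep(TRUE, n)

  band <- age_band_index(records$age)
  out_of <- function(x, lim) !is.na(x) & (x < lim[band, 1] | x > lim[band, 2])
  reason <- rep(NA_character_, n)
  bad_bmi <- out_of(bmi, rules$bmi)
  reason[bad_bmi] <- "bmi_range"
  bad_w <- out_of(weight, rules$weight)
  reason[bad_w] <- "weight_range"
  bad_h <- out_of(height, rules$height)
  reason[bad_h] <- "height_range"
  if (rules$require_single_year_age_under18)
    reason[records$age < 18 & !single] <- "age_reporting"
  if (rules$exclude_pregnant) reason[pregnant] <- "pregnancy"

  keep <- is.na(reason)
  excluded <- records[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  log <- table(factor(reason[!keep],
                      levels = c("pregnancy", "age_reporting", "height_range",
                                 "weight_range", "bmi_range")))
  list(retained = records[keep, , drop = FALSE],
       excluded = excluded,
       log = c(log))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Write an exclusion log as JSON
#'
#' @param cleaned result of [apply_cleaning_rules()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_exclusion_log <- function(cleaned, path) {
  jsonlite::write_json(list(n_retained = nrow(cleaned$retained),
                            n_excluded = nrow(cleaned$excluded),
                            by_reason = as.list(cleaned$log)),
                       path, auto_unbox = TRUE)
  invisible(path)
}
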