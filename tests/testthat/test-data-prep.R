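make_records <- function() {
  data.frame(
    study_id = "s1",
    sex = rep(c("female", "male"), 5),
    age = c(9, 30, 45, 12, 16, 30, 30, 55, 9, 70),
    height = c(59, 170, 165, 150, 170, 170, 168, 160, 120, 165),
    weight = c(20, 80, 70, 45, 65, 72, 300, 60, 25, 70),
    pregnant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    single_year_age = TRUE,
    stringsAsFactors = FALSE)
}

test_that("cleaning rules exclude by the printed plausibility ranges", {
  # child of 9 with height 59 cm is below the under-10 lower limit
  one <- data.frame(study_id = "a", sex = "female", age = 9, height = 59,
                    weight = 20, pregnant = FALSE, single_year_age = TRUE)
  out <- apply_cleaning_rules(one)
  expect_equal(nrow(out$retained), 0)
  expect_equal(out$excluded$reason, "height_range")
  # unremarkable adult is retained
  two <- data.frame(study_id = "a", sex = "male", age = 30, height = 170,
                    weight = 80, pregnant = FALSE, single_year_age = TRUE)
  expect_equal(nrow(apply_cleaning_rules(two)$retained), 1)
})

test_that("toy table with planted violations yields the expected log", {
  rec <- make_records()
  # planted: row 1 height_range (age 9, 59 cm), row 3 pregnancy,
  # row 7 bmi_range (bmi 106 > 80 for age >= 15; weight 300 is at the limit)
  out <- apply_cleaning_rules(rec)
  expect_equal(nrow(out$retained), 7)
  expect_equal(unname(out$log[c("pregnancy", "height_range", "bmi_range")]),
               c(1L, 1L, 1L))
  expect_equal(sum(out$log), nrow(rec) - nrow(out$retained))
})

test_that("cleaning is idempotent and flags bad inputs", {
  rec <- make_records()
  once <- apply_cleaning_rules(rec)
  twice <- apply_cleaning_rules(once$retained)
  expect_equal(twice$retained, once$retained)
  expect_equal(sum(twice$log), 0)
  bad_sex <- transform(make_records(), sex = "other")
  expect_error(apply_cleaning_rules(bad_sex), "err_sex")
  bad_neg <- make_records(); bad_neg$weight[2] <- -5
  expect_error(apply_cleaning_rules(bad_neg), "err_negative")
})

test_that("under-18 records need single-year ages", {
  rec <- data.frame(study_id = "a", sex = "female", age = c(12, 30),
                    height = c(150, 165), weight = c(40, 60),
                    pregnant = FALSE, single_year_age = c(FALSE, FALSE))
  out <- apply_cleaning_rules(rec)
  expect_equal(out$excluded$age[1], 12)
  expect_equal(out$excluded$reason, "age_reporting")
  expect_equal(nrow(out$retained), 1)
})

test_that("adult categories use half-open bands", {
  sch <- bmi_category_scheme("adult")
  expect_equal(assign_bmi_category(40, "female", 32, sch), "30to35")
  expect_equal(assign_bmi_category(40, "female", 18.5, sch), "18_5to20")
  expect_equal(assign_bmi_category(40, "female", 40, sch), "gte40")
  expect_equal(assign_bmi_category(40, "female", 12, sch), "lt18_5")
  # the bands partition: exactly one category for any BMI in [6, 80]
  grid <- seq(6, 80, by = 0.01)
  cats <- assign_bmi_category(rep(40, length(grid)), "female", grid, sch)
  expect_false(anyNA(cats))
  expect_equal(length(cats), length(grid))
})

test_that("child categories use LMS z-scores with strict obesity cut", {
  ref <- synthetic_growth_reference()
  sch <- bmi_category_scheme("child_adolescent", reference = ref)
  row <- ref[ref$sex == "female" & ref$age == 10, ]
  bmi_at <- function(z) row$M * (1 + row$L * row$S * z)^(1 / row$L)
  expect_equal(assign_bmi_category(10, "female", bmi_at(2), sch), "z1_2")
  expect_equal(assign_bmi_category(10, "female", bmi_at(2.01), sch), "zgt2")
  expect_equal(assign_bmi_category(10, "female", bmi_at(0), sch), "zm1_1")
  expect_equal(assign_bmi_category(10, "female", bmi_at(-2.5), sch), "zlt_m2")
  expect_error(assign_bmi_category(4, "female", 15, sch), "age = 4")
})

test_that("aggregation reduces to raw counts without weights", {
  set.seed(2)
  n <- 100
  rec <- data.frame(study_id = "s1", sex = "female", age = 30,
                    bmi = c(rep(32, 12), rep(22, 88)))
  sch <- bmi_category_scheme("adult")
  obs <- aggregate_observations(rec, sch)
  row <- obs[obs$category == "30to35", ]
  expect_equal(row$y, 12)
  expect_equal(row$n, 100)
  # equal weights give the identical result
  rec$survey_weight <- 2.5
  obs_w <- aggregate_observations(rec, sch)
  expect_equal(obs_w$y, obs$y)
  expect_equal(obs_w$n, obs$n)
})

test_that("aggregation conserves prevalence mass across categories", {
  set.seed(3)
  rec <- data.frame(study_id = rep(c("s1", "s2"), each = 60),
                    sex = "female", age = rep(c(30, 50), 60),
                    bmi = runif(120, 15, 45),
                    survey_weight = runif(120, 0.5, 2))
  sch <- bmi_category_scheme("adult")
  obs <- aggregate_observations(rec, sch)
  mass <- tapply(obs$phat, paste(obs$study_id, obs$age_group), sum)
  expect_true(all(abs(mass - 1) < 1e-9))
})

test_that("design-based effective sample size matches a hand linearization", {
  # 2 clusters, one stratum, stated weights; oracle computed directly from
  # the linearized variance of the ratio mean
  rec <- data.frame(study_id = "s1", sex = "female", age = 30,
                    bmi = c(32, 32, 22, 22, 32, 22, 22, 22),
                    survey_weight = c(2, 1, 1, 2, 1, 1, 2, 2),
                    stratum = 1L,
                    cluster = c(1, 1, 1, 1, 2, 2, 2, 2))
  sch <- bmi_category_scheme("adult")
  obs <- aggregate_observations(rec, sch)
  row <- obs[obs$category == "30to35", ]
  w <- rec$survey_weight
  yind <- as.numeric(rec$bmi >= 30 & rec$bmi < 35)
  phat <- sum(w * yind) / sum(w)
  z <- w * (yind - phat) / sum(w)
  zc <- tapply(z, rec$cluster, sum)
  vhat <- 2 / 1 * sum((zc - mean(zc))^2)
  n_eff_oracle <- phat * (1 - phat) / vhat
  expect_equal(row$n, n_eff_oracle, tolerance = 1e-9)
  expect_equal(row$y, floor(phat * n_eff_oracle + 0.5))
})

test_that("degenerate prevalences fall back to counts", {
  rec <- data.frame(study_id = "s1", sex = "female", age = 30,
                    bmi = rep(22, 10), survey_weight = runif(10, 1, 2),
                    stratum = 1L, cluster = rep(1:2, 5))
  sch <- bmi_category_scheme("adult")
  obs <- aggregate_observations(rec, sch)
  expect_true(all(obs$n == 10))
  expect_equal(obs$y[obs$category == "20to25"], 10)
})

test_that("exclusion log round-trips through JSON", {
  out <- apply_cleaning_rules(make_records())
  path <- tempfile(fileext = ".json")
  write_exclusion_log(out, path)
  log <- jsonlite::read_json(path)
  expect_equal(log$n_retained, nrow(out$retained))
  expect_equal(log$by_reason$pregnancy, 1L)
})
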