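#' Aggregate cleaned records to binomial observation rows
#'
#' Collapses individual records to one row per (study, sex, age group,
#' category) holding the weighted category prevalence and an effective
#' binomial denominator. Ages 5-19 are grouped in single years; ages 20 and
#' above in 5-year bands (top band open-ended at `top_age`).
#'
#' With survey weights and design identifiers (stratum, cluster) present, the
#' weighted prevalence \eqn{\hat p = \sum w y / \sum w} gets a design-based
#' variance by Taylor-series linearization over clusters within strata, and
#' the effective sample size bridging to the binomial likelihood is
#' \eqn{n_{eff} = \hat p (1 - \hat p) / \widehat{var}(\hat p)}, with numerator
#' \eqn{y = round(\hat p \, n_{eff})} (round half up). When \eqn{\hat p} is 0
#' or 1, or no design metadata is present, \eqn{n_{eff}} falls back to the
#' (weighted) count. With equal weights and no clustering the row reduces to
#' the raw (y, n) count.
#'
#' @param records cleaned participant records (see [apply_cleaning_rules()]);
#'   must include study_id, sex, age and bmi (or height and weight).
#' @param scheme a [bmi_category_scheme()].
#' @param design data frame mapping study_id to coverage
#'   ("national"/"subnational"/"community"), urban_scope
#'   ("both"/"urban"/"rural"), year, country and country_urbanization; merged
#'   onto the output rows.
#' @param top_age lower edge of the open-ended adult age band (default 85).
#' @return data frame of observation rows with columns study_id, country,
#'   year, sex, age_group, mid_age, category, y, n, coverage, urban_scope,
#'   country_urbanization.
#' @export
aggregate_observations <- function(records, scheme, design = NULL, top_age = 85) {
  stopifnot(is.data.frame(records))
  bmi <- records$bmi
  if (is.null(bmi)) bmi <- records$weight / (records$height / 100)^2
  category <- assign_bmi_category(records$age, records$sex, bmi, scheme)
  ag <- age_group_of(records$age, top_age)
  w <- if ("survey_weight" %in% names(records)) records$survey_weight else rep(1, nrow(records))
  if (any(w < 0)) stop("survey weights must be nonnegative")
  stratum <- if ("stratum" %in% names(records)) records$stratum else NULL
  cluster <- if ("cluster" %in% names(records)) records$cluster else NULL
  has_design <- !is.null(cluster)

  cells <- split(seq_len(nrow(records)),
                 list(study = records$study_id, sex = records$sex, ag = ag$label),
                 drop = TRUE)
  out <- lapply(cells, function(idx) {
    rows <- lapply(scheme$labels, function(cat) {
      yind <- as.numeric(category[idx] == cat)
      phat <- sum(w[idx] * yind) / sum(w[idx])
      if (has_design && phat > 0 && phat < 1) {
        v <- linearized_ratio_variance(yind, w[idx],
                                       strata = if (is.null(stratum)) rep(1L, length(idx)) else stratum[idx],
                                       clusters = cluster[idx])
        # degenerate designs (a single cluster) yield v = 0: fall back to count
        n_eff <- if (is.finite(v) && v > 0) phat * (1 - phat) / v else length(idx)
      } else {
        # no design metadata, or phat in {0,1} (continuity rule): raw count
        n_eff <- length(idx)
      }
      data.frame(study_id = records$study_id[idx][1],
                 sex = records$sex[idx][1],
                 age_group = ag$label[idx][1],
                 mid_age = ag$mid[idx][1],
                 category = cat,
                 phat = phat,
                 y = round_half_up(phat * n_eff),
                 n = n_eff)
    })
    do.call(rbind, rows)
  })
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  if (!is.null(design)) {
    obs <- merge(obs, design, by = "study_id", sort = FALSE)
  }
  obs
}

# Taylor-series linearization variance of a weighted ratio mean under
# with-replacement sampling of clusters within strata:
#   z_k = w_k (y_k - phat) / sum(w); cluster totals per stratum;
#   var = sum_h n_h/(n_h - 1) sum_c (z_hc - mean_h)^2
linearized_ratio_variance <- function(y, w, strata, clusters) {
  W <- sum(w)
  phat <- sum(w * y) / W
  z <- w * (y - phat) / W
  zt <- tapply(z, list(strata, clusters), sum)  # cluster totals (NA where empty)
  v <- 0
  for (h in rownames(zt)) {
    zh <- zt[h, ]
    zh <- zh[!is.na(zh)]
    nh <- length(zh)
    if (nh >= 2) v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  v
}

round_half_up <- function(x) floor(x + 0.5)

#' Age grouping for observation rows
#'
#' Single-year groups for ages 5-19 and 5-year groups from 20, with an
#' open-ended top band starting at `top_age` whose nominal mid-age is
#' `top_age + 2.5`.
#'
#' @param age numeric vector of ages in years.
#' @param top_age lower edge of the open-ended band.
#' @return list of vectors `label` and `mid`.
#' @export
age_group_of <- function(age, top_age = 85) {
  lab <- character(length(age)); mid <- numeric(length(age))
  young <- age < 20
  lab[young] <- sprintf("%d", floor(age[young]))
  mid[young] <- floor(age[young]) + 0.5
  old <- !young
  lo <- pmin(20 + 5 * floor((age[old] - 20) / 5), top_age)
  lab[old] <- ifelse(lo >= top_age, sprintf("%dplus", top_age),
                     sprintf("%d-%d", lo, lo + 4))
  mid[old] <- ifelse(lo >= top_age, top_age + 2.5, lo + 2.5)
  list(label = lab, mid = mid)
}
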