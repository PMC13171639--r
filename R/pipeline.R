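#' Read / write observation tables
#'
#' Observation tables are plain CSV with documented columns: study_id,
#' country, year, sex, mid_age, category, y, n, coverage, urban_scope,
#' country_urbanization.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_observation_csv <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "country", "year", "mid_age", "category", "y", "n",
            "coverage", "urban_scope", "country_urbanization")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("observation CSV missing columns: ", paste(miss, collapse = ", "))
  obs
}

#' @rdname read_observation_csv
#' @param obs observation table.
#' @export
write_observation_csv <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param output_dir directory for artifacts.
#' @param population "adult" or "child_adolescent".
#' @param sex label recorded in outputs.
#' @param simulation a [simulation_config()] (synthetic route), or NULL with
#'   `input_csv` set (ingest route).
#' @param input_csv observation-table CSV when not simulating.
#' @param sampler a [sampler_config()].
#' @param std_population a [standard_population()]; equal weights over the
#'   prediction age grid by default.
#' @param mid_ages prediction age grid; defaults to the simulation grid.
#' @param clustering list(k, n_starts, components, subsample_props,
#'   n_subsamples) or NULL to skip.
#' @param validation list(design, fraction, replicates) or NULL to skip.
#' @param seed master seed recorded in every artifact's metadata.
#' @param rhat_threshold,rhat_fraction convergence gate: the run passes when
#'   more than `rhat_fraction` of country-year-age outcomes have split-Rhat
#'   below `rhat_threshold`.
#' @return object of class "run_config".
#' @export
run_config <- function(output_dir, population = "adult", sex = "female",
                       simulation = simulation_config(), input_csv = NULL,
                       sampler = sampler_config(),
                       std_population = NULL, mid_ages = NULL,
                       clustering = list(k = 6, n_starts = 50, components = 3,
                                         subsample_props = 0.9, n_subsamples = 100),
                       validation = NULL, seed = 1L,
                       rhat_threshold = 1.05, rhat_fraction = 0.99) {
  if (is.null(simulation) && is.null(input_csv))
    stop("config needs either a simulation config or an input CSV [exit 2]")
  if (!is.null(simulation) && !inherits(simulation, "simulation_config"))
    stop("simulation must be a simulation_config [exit 2]")
  structure(as.list(environment()), class = "run_config")
}

# hash of the scientific configuration; file-system locations are excluded so
# the same analysis in a different directory carries the same identity
config_hash <- function(config) {
  keep <- setdiff(names(config), c("output_dir", "input_csv"))
  f <- tempfile()
  dput(lapply(unclass(config)[keep], function(x) if (is.list(x)) unclass(x) else x),
       file = f)
  unname(tools::md5sum(f))
}

write_artifact <- function(df, path, meta) {
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> fit per category -> post-process ->
#' cluster -> (optional) validate, writing tidy CSV artifacts plus a JSON
#' manifest listing every artifact with its MD5 content hash, the master
#' seed, the config hash, and the split-Rhat convergence gate result
#' (pass when more than the configured fraction of country-year-age outcomes
#' have split-Rhat below the threshold). Every artifact gets a sidecar
#' `.meta.json` with the config hash and seed.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly written to
#'   `file.path(output_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(config)
  meta <- list(config_hash = chash, seed = config$seed,
               version = as.character(utils::packageVersion("bmitrend")))
  manifest <- list(config_hash = chash, seed = config$seed, stages = list(),
                   artifacts = list())
  add_artifact <- function(stage, path) {
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <<- list(
      stage = stage, path = path, md5 = unname(tools::md5sum(path)))
  }

  ## stage: simulate or ingest
  if (!is.null(config$simulation)) {
    world <- generate_world(config$simulation)
    obs <- simulate_observations(world, sex = config$sex)
    hierarchy <- world$hierarchy
    T <- config$simulation$T
    mid_ages <- config$mid_ages %||% config$simulation$mid_ages
    p <- write_artifact(obs, file.path(config$output_dir, "observations.csv"), meta)
    add_artifact("simulate", p)
  } else {
    obs <- read_observation_csv(config$input_csv)
    world <- NULL
    hierarchy <- attr(obs, "hierarchy") %||%
      balanced_hierarchy(max(obs$country), max(1, max(obs$country) %/% 3), 1)
    T <- max(obs$year)
    mid_ages <- config$mid_ages %||% sort(unique(obs$mid_age))
  }
  manifest$stages$data <- list(rows = nrow(obs), studies = length(unique(obs$study_id)))

  ## stage: fit per category
  cats <- unique(obs$category)
  fits <- list(); surfaces <- list(); rhat_frac <- numeric(0)
  for (cat in cats) {
    fit <- fit_prevalence_model(obs[obs$category == cat, , drop = FALSE],
                                hierarchy, T, population = config$population,
                                config = config$sampler)
    fits[[cat]] <- fit
    surfaces[[cat]] <- predict_prevalence_draws(fit, mid_ages)
    cs <- convergence_summary(fit, mid_ages)
    rhat_frac[cat] <- cs$fraction_below
  }
  gate_pass <- all(rhat_frac > config$rhat_fraction)
  manifest$stages$fit <- list(categories = cats,
                              rhat_fraction_below = as.list(rhat_frac),
                              convergence_gate = if (gate_pass) "pass" else "fail")

  ## stage: post-process
  if (length(cats) > 1) {
    resc <- rescale_and_obesity(surfaces, obesity_categories =
                                  intersect(c("30to35", "35to40", "gte40", "zgt2", "obesity"), cats))
    ob <- resc$obesity
  } else {
    ob <- surfaces[[1]]
  }
  std <- config$std_population %||%
    standard_population(seq_along(mid_ages), rep(1, length(mid_ages)))
  std_series <- age_standardize(ob, std)
  vel <- velocity_series(std_series)
  prev_tab <- do.call(rbind, lapply(seq_along(cats), function(i)
    prevalence_summary_table(surfaces[[i]], sex = config$sex, category = cats[i])))
  p <- write_artifact(prev_tab, file.path(config$output_dir, "prevalence.csv"), meta)
  add_artifact("postprocess", p)
  vel_tab <- do.call(rbind, lapply(seq_len(dim(vel)[2]), function(j) {
    do.call(rbind, lapply(seq_len(dim(vel)[3]), function(t) {
      s <- posterior_summaries(vel[, j, t])
      data.frame(sex = config$sex, country = j,
                 terminal_year = dimnames(vel)[[3]][t], mean = s$mean,
                 l95 = s$lower, u95 = s$upper, pp_positive = s$pp_positive)
    }))
  }))
  p <- write_artifact(vel_tab, file.path(config$output_dir, "velocity.csv"), meta)
  add_artifact("postprocess", p)
  manifest$stages$postprocess <- list(countries = dim(ob)[2], years = dim(ob)[3])

  ## stage: cluster
  if (!is.null(config$clustering)) {
    traj <- apply(std_series, c(2, 3), mean)   # countries x years posterior mean
    rownames(traj) <- paste0("country", seq_len(nrow(traj)))
    pp <- preprocess_trajectories(traj)
    k <- min(config$clustering$k, nrow(pp$processed) - 1)
    pca <- pca_reduce(pp$processed,
                      n_components = min(config$clustering$components,
                                         nrow(pp$processed) - 1))
    alloc <- kmeans_allocate(pca$scores, k = k,
                             n_starts = config$clustering$n_starts,
                             seed = config$seed, raw = traj)
    stab <- jaccard_stability(pca$scores, k = k,
                              proportions = config$clustering$subsample_props,
                              n_subsamples = config$clustering$n_subsamples,
                              seed = config$seed,
                              n_starts = config$clustering$n_starts)
    alloc_tab <- data.frame(country = names(alloc$cluster),
                            cluster = unname(alloc$cluster),
                            typology = alloc$typology[alloc$cluster])
    p <- write_artifact(alloc_tab, file.path(config$output_dir, "clusters.csv"), meta)
    add_artifact("cluster", p)
    p <- write_artifact(as.data.frame(stab),
                        file.path(config$output_dir, "cluster_stability.csv"), meta)
    add_artifact("cluster", p)
    manifest$stages$cluster <- list(k = k, inertia = alloc$inertia)
  }

  ## stage: validate (synthetic route only)
  if (!is.null(config$validation) && !is.null(config$simulation)) {
    reps <- config$validation$replicates %||% 1L
    reports <- lapply(seq_len(reps), function(r)
      validate_self_consistency(config$simulation,
                                config$validation$sampler %||% config$sampler,
                                design = config$validation$design %||% "test2_sources",
                                fraction = config$validation$fraction %||% 0.10,
                                replicate = r, seed = config$seed)$report)
    val_tab <- do.call(rbind, Map(function(rep, r) {
      rep$replicate <- r; rep
    }, reports, seq_len(reps)))
    p <- write_artifact(val_tab, file.path(config$output_dir, "validation.csv"), meta)
    add_artifact("validate", p)
    manifest$stages$validate <- list(replicates = reps)
  }

  manifest$convergence_gate <- if (gate_pass) "pass" else "fail"
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Split-Rhat summary over country-year-age outcomes
#'
#' Computes split-Rhat for the posterior prevalence of every country-year-age
#' cell using the per-chain draws (thinned to at most `max_draws` per chain)
#' and reports the fraction of outcomes below the threshold together with the
#' 97.5th percentile of the Rhat distribution.
#'
#' @param fit a [fit_prevalence_model()] result.
#' @param mid_ages prediction age grid.
#' @param threshold split-Rhat threshold (default 1.05).
#' @param max_draws per-chain draws used (evenly thinned).
#' @return list: fraction_below, q975, rhat (array country x year x age).
#' @export
convergence_summary <- function(fit, mid_ages, threshold = 1.05, max_draws = 250) {
  nch <- length(fit$chains)
  n <- nrow(fit$chains[[1]]$hyper)
  cnt <- min(max_draws, n)
  idx <- ceiling(seq_len(cnt) * n / cnt)
  pers <- lapply(fit$chains, function(ch) {
    d <- list(a = ch$a[idx, , drop = FALSE], b = ch$b[idx, , drop = FALSE],
              u = ch$u[idx, , drop = FALSE], psi = ch$psi[idx, , drop = FALSE],
              phi = if (!is.null(ch$phi)) ch$phi[idx, , drop = FALSE] else NULL,
              hyper = ch$hyper[idx, , drop = FALSE])
    predict_prevalence_draws(fit, mid_ages, draws = d)
  })
  dims <- dim(pers[[1]])[2:4]
  rhat <- array(NA_real_, dims)
  for (j in seq_len(dims[1])) for (t in seq_len(dims[2])) for (hh in seq_len(dims[3])) {
    m <- vapply(pers, function(p) p[, j, t, hh], numeric(cnt))
    rhat[j, t, hh] <- as.numeric(split_rhat(m))
  }
  list(fraction_below = mean(rhat < threshold),
       q975 = stats::quantile(rhat, 0.975, names = FALSE),
       rhat = rhat)
}
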