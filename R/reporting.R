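#' Box-Cox transform with maximum-likelihood lambda
#'
#' Profiles the Box-Cox likelihood of a one-sample model over a lambda
#' grid (via [MASS::boxcox()]), refines the maximum, and returns the
#' transformed values `(x^lambda - 1)/lambda` (or `log x` at lambda = 0).
#' Used to symmetrize the strongly right-skewed obstacle-repulsion
#' parameter before summaries.
#'
#' @param values Strictly positive numeric vector.
#' @param lambda_grid Grid over which the likelihood is profiled.
#' @param lambda Optional fixed lambda, skipping the MLE step.
#' @return A list with `transformed` and `lambda`.
#' @export
boxcox_transform <- function(values, lambda_grid = seq(-3, 3, by = 0.01),
                             lambda = NULL) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("Box-Cox requires strictly positive finite values")
  if (is.null(lambda)) {
    if (length(unique(values)) < 2) {
      lambda <- 1
    } else {
      prof <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
      lambda <- prof$x[which.max(prof$y)]
    }
  }
  transformed <- if (abs(lambda) < 1e-8) log(values)
  else (values^lambda - 1) / lambda
  list(transformed = transformed, lambda = lambda)
}

#' Descriptive summaries of fitted parameters
#'
#' Per-group mean, SD, min, max, skewness and kurtosis of beta, gamma,
#' epsilon and Box-Cox-transformed epsilon, in a tidy table ready for
#' external mixed-model analysis.
#'
#' @param params A data.frame with columns `beta`, `gamma`, `epsilon` and
#'   the grouping columns named in `by`.
#' @param by Character vector of grouping column names (e.g.
#'   `c("profile", "route_type")`).
#' @return A tidy data.frame: one row per group x parameter with
#'   `n`, `mean`, `sd`, `min`, `max`, `skewness`, `kurtosis`.
#' @export
summarize_params <- function(params, by = "profile") {
  stopifnot(all(c("beta", "gamma", "epsilon") %in% names(params)),
            all(by %in% names(params)), nrow(params) > 0)
  params$epsilon_boxcox <- boxcox_transform(params$epsilon)$transformed
  value_cols <- c("beta", "gamma", "epsilon", "epsilon_boxcox")
  key <- interaction(params[by], drop = TRUE, sep = "|")
  rows <- list()
  for (g in levels(key)) {
    sub <- params[key == g, ]
    labels <- sub[1, by, drop = FALSE]
    for (v in value_cols) {
      x <- sub[[v]]
      rows[[length(rows) + 1]] <- cbind(labels, data.frame(
        parameter = v, n = length(x), mean = mean(x),
        sd = if (length(x) > 1) sd(x) else 0,
        min = min(x), max = max(x),
        skewness = if (length(x) > 2) e1071::skewness(x) else NA_real_,
        kurtosis = if (length(x) > 3) e1071::kurtosis(x) else NA_real_,
        row.names = NULL))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end pipeline with the task's canonical
#' defaults (10 m/s, 25 deg/s, 62.5 deg/s^2, 50 Hz, 20 s duration filter,
#' 1.2x length filter, 0.2 m bins, 10% route threshold, 95% CI band).
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed.
#' @param n_configs Number of random obstacle configurations.
#' @param n_obstacles Obstacles per configuration.
#' @param n_agents_per_profile Agents per population profile.
#' @param reps Repetitions per agent x scenario.
#' @param n_fits Number of trajectories to fit in the fitting stage (kept
#'   small by default; fitting is the expensive stage).
#' @param fit_control Optimizer control list for [fit_dpmp()].
#' @param constants A [dpmp_constants()].
#' @param kin A [kinematics_spec()].
#' @param profiles List of [population_profile()] objects.
#' @param t_max Episode cap for generated trials (s).
#' @param max_duration,length_factor Admissibility filter settings.
#' @param bin_width Binning width (m).
#' @param ci_level CI band level (percent).
#' @param route_threshold Preferred-route share threshold.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("routenav_run_"), seed = 1,
                       n_configs = 3, n_obstacles = 9,
                       n_agents_per_profile = 4, reps = 6, n_fits = 2,
                       fit_control = list(pop_size = 20, max_iter = 30),
                       constants = dpmp_constants(),
                       kin = kinematics_spec(),
                       profiles = list(population_profile("human_like"),
                                       population_profile("drl_like")),
                       t_max = 30, max_duration = 20, length_factor = 1.2,
                       bin_width = 0.2, ci_level = 95,
                       route_threshold = 0.10) {
  structure(list(out_dir = out_dir, seed = seed, n_configs = n_configs,
                 n_obstacles = n_obstacles,
                 n_agents_per_profile = n_agents_per_profile, reps = reps,
                 n_fits = n_fits, fit_control = fit_control,
                 constants = constants, kin = kin, profiles = profiles,
                 t_max = t_max,
                 max_duration = max_duration, length_factor = length_factor,
                 bin_width = bin_width, ci_level = ci_level,
                 route_threshold = route_threshold),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes generate -> preprocess -> metrics -> fit -> summarize, writing
#' tidy CSV tables and a JSON manifest (inputs, seed, output hashes) under
#' `config$out_dir`. Stages log their counts; any failure halts with the
#' stage name.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the main in-memory results (`dataset`,
#'   `binned`, `distances`, `ci`, `fits`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- gen-data ------------------------------------------------------
  dataset <- stage("gen-data", {
    configs <- lapply(seq_len(config$n_configs), function(i)
      random_obstacle_config(config$n_obstacles, seed = config$seed * 1000 + i))
    names(configs) <- sprintf("config%02d", seq_len(config$n_configs))
    scen <- enumerate_scenarios(configs)
    for (nm in names(scen))
      write_scenario_json(scen[[nm]],
                          file.path(config$out_dir, paste0(nm, ".json")))
    ds <- generate_dataset(config$profiles, config$n_agents_per_profile,
                           scen, reps = config$reps, seed = config$seed,
                           constants = config$constants, kin = config$kin,
                           t_max = config$t_max)
    ds$scenarios <- scen
    say("gen-data: %d trials (%d excluded after retries)",
        nrow(ds$trials), sum(ds$trials$excluded))
    ds
  })
  write.csv(dataset$trials, file.path(config$out_dir, "trials.csv"),
            row.names = FALSE)
  write.csv(dataset$agents, file.path(config$out_dir, "agents.csv"),
            row.names = FALSE)

  # --- preprocess ----------------------------------------------------
  pp <- stage("preprocess", {
    ok <- !dataset$trials$excluded &
      dataset$trials$outcome == "reached_target"
    trials <- dataset$trajectories[dataset$trials$trial_id[ok]]
    flt <- filter_trials(trials,
                         scenario_ids = dataset$trials$scenario_id[ok],
                         max_duration = config$max_duration,
                         length_factor = config$length_factor)
    kept_ids <- dataset$trials$trial_id[ok][flt$report$kept]
    binned <- lapply(seq_along(flt$kept), function(i) {
      b <- bin_by_y(resample_to_n(flt$kept[[i]], 1000),
                    bin_width = config$bin_width)
      b$source_id <- kept_ids[i]
      b
    })
    names(binned) <- kept_ids
    say("preprocess: kept %d / %d trials after filters",
        length(binned), length(trials))
    list(binned = binned, report = flt$report, kept_ids = kept_ids)
  })
  write.csv(pp$report, file.path(config$out_dir, "filter_report.csv"),
            row.names = FALSE)

  # --- metrics -------------------------------------------------------
  metrics <- stage("metrics", {
    lab <- dataset$trials[match(pp$kept_ids, dataset$trials$trial_id),
                          c("trial_id", "agent_id", "profile", "scenario_id",
                            "route_type")]
    names(lab)[names(lab) == "profile"] <- "group"
    dist <- aggregate_distances(pp$binned, lab)
    ci <- list()
    for (sc in unique(lab$scenario_id)) {
      hum <- pp$binned[lab$trial_id[lab$scenario_id == sc &
                                      lab$group == "human_like"]]
      drl <- pp$binned[lab$trial_id[lab$scenario_id == sc &
                                      lab$group == "drl_like"]]
      if (length(hum) >= 2 && length(drl) >= 1) {
        band <- ci_band(hum, level = config$ci_level)
        ci[[sc]] <- data.frame(
          scenario_id = sc,
          containment = ci_containment(group_mean(drl), band),
          n_human = length(hum), n_drl = length(drl))
      }
    }
    ci <- if (length(ci)) do.call(rbind, ci) else NULL
    say("metrics: %d pair distances, %d scenarios with CI containment",
        nrow(dist$records), if (is.null(ci)) 0L else nrow(ci))
    list(dist = dist, ci = ci)
  })
  write.csv(metrics$dist$records,
            file.path(config$out_dir, "distance_records.csv"),
            row.names = FALSE)
  write.csv(metrics$dist$aggregates,
            file.path(config$out_dir, "distance_aggregates.csv"),
            row.names = FALSE)
  if (!is.null(metrics$ci))
    write.csv(metrics$ci, file.path(config$out_dir, "ci_containment.csv"),
              row.names = FALSE)

  # --- fit -----------------------------------------------------------
  fits <- stage("fit", {
    ids <- head(pp$kept_ids, config$n_fits)
    out <- list()
    for (k in seq_along(ids)) {
      id <- ids[k]
      row <- dataset$trials[dataset$trials$trial_id == id, ]
      sc <- dataset$scenarios[[row$scenario_id]]
      out[[id]] <- fit_dpmp(dataset$trajectories[[id]], sc,
                            constants = config$constants,
                            seed = config$seed + k,
                            control = config$fit_control,
                            trajectory_id = id)
    }
    say("fit: fitted %d trajectories", length(out))
    out
  })
  if (length(fits)) {
    fit_tab <- do.call(rbind, lapply(names(fits), function(id) {
      f <- fits[[id]]
      data.frame(trial_id = id, beta = f$par["beta"], gamma = f$par["gamma"],
                 epsilon = f$par["epsilon"], dtw_error = f$dtw_error,
                 converged = f$optimizer$converged, row.names = NULL)
    }))
    write.csv(fit_tab, file.path(config$out_dir, "fits.csv"),
              row.names = FALSE)
  }

  # --- summarize -----------------------------------------------------
  summary_tab <- stage("summarize", {
    ag <- dataset$agents
    summarize_params(ag, by = "profile")
  })
  write.csv(summary_tab, file.path(config$out_dir, "parameter_summary.csv"),
            row.names = FALSE)

  # --- manifest ------------------------------------------------------
  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(seed = config$seed,
                   n_configs = config$n_configs,
                   n_agents_per_profile = config$n_agents_per_profile,
                   reps = config$reps,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   outputs = setNames(as.list(unname(tools::md5sum(files))),
                                      basename(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = dataset, binned = pp$binned,
                 distances = metrics$dist, ci = metrics$ci, fits = fits,
                 summary = summary_tab, manifest = manifest))
}
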