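## Configuration, file I/O and reproducibility plumbing.  Experiments are
## described by a YAML config with a published schema, validated before any
## computation; every run writes its resolved config (defaults filled in)
## beside its outputs, and every numeric output file carries a JSON sidecar
## with provenance metadata (config hash, seed, package version).
##
## CSV dialect: '.' decimal, comma delimiter, UTF-8, mandatory header row;
## scientific notation permitted.

experiment_modes <- c("simulate-sde", "solve-fpe", "sample-mechanism",
                      "analyze", "recover")

## allowed keys, per mode (TRUE = required)
config_schema <- list(
  common = c(mode = TRUE, seed = TRUE, out_dir = FALSE, verbose = FALSE),
  `simulate-sde` = c(model = TRUE, initial = TRUE, grid = TRUE,
                     n_paths = TRUE, scheme = FALSE, format = FALSE),
  `solve-fpe` = c(model = TRUE, initial = TRUE, fpe = TRUE),
  `sample-mechanism` = c(mechanism = TRUE),
  analyze = c(input = TRUE, dialect = FALSE, alpha = FALSE, method = FALSE),
  recover = c(input = TRUE, dialect = FALSE, model = FALSE, n_boot = FALSE)
)

config_defaults <- list(
  out_dir = ".", verbose = FALSE, scheme = "exact", format = "wide",
  dialect = "single-column", alpha = 0.05, method = "shapiro", n_boot = 500
)

fail_config <- function(fmt, ...) {
  stop(sprintf(paste0("config error: ", fmt), ...), call. = FALSE)
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), names(allowed))
  if (length(unknown))
    fail_config("unknown key(s) in %s: %s", where,
                paste(unknown, collapse = ", "))
  missing <- names(allowed)[allowed & !(names(allowed) %in% names(x))]
  if (length(missing))
    fail_config("missing required key(s) in %s: %s", where,
                paste(missing, collapse = ", "))
}

config_rate <- function(model) {
  check_keys(model, c(mu_k = TRUE, sigma_k = TRUE, direction = FALSE),
             "model")
  if (!is.null(model$sigma_k) && is.numeric(model$sigma_k) &&
      length(model$sigma_k) == 1L && model$sigma_k < 0)
    fail_config("model.sigma_k must be >= 0 (got %g)", model$sigma_k)
  rate_model(model$mu_k, model$sigma_k,
             direction = model$direction %||% "sink")
}

config_initial <- function(initial) {
  if (!is.null(initial$x0)) {
    check_keys(initial, c(x0 = TRUE), "initial")
    return(initial_log_params(initial$x0))
  }
  check_keys(initial, c(mu = TRUE, sigma2 = TRUE), "initial")
  lognormal_params(initial$mu, initial$sigma2)
}

config_lognormal_list <- function(lst, where) {
  if (!is.list(lst) || !length(lst))
    fail_config("%s must be a non-empty list of {mu, sigma2}", where)
  lapply(seq_along(lst), function(i) {
    check_keys(lst[[i]], c(mu = TRUE, sigma2 = TRUE, replicate = FALSE),
               sprintf("%s[%d]", where, i))
    lst[[i]]
  })
  comps <- list()
  for (i in seq_along(lst)) {
    p <- lognormal_params(lst[[i]]$mu, lst[[i]]$sigma2)
    r <- lst[[i]]$replicate %||% 1L
    comps <- c(comps, replicate_components(p, r))
  }
  comps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate an experiment configuration
#'
#' Reads a YAML experiment config, rejects unknown keys, fills documented
#' defaults and validates all fields before any computation.  See the
#' package vignette for the full schema; the `mode` key selects among
#' `simulate-sde`, `solve-fpe`, `sample-mechanism`, `analyze` and `recover`.
#'
#' @param path Path to a YAML file.
#' @return The resolved config (class `experiment_config`).
#' @seealso [run_experiment()]
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) fail_config("config file not found: %s", path)
  validate_experiment_config(yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @param config A named list as parsed from YAML.
#' @export
validate_experiment_config <- function(config) {
  if (!is.list(config) || is.null(config$mode))
    fail_config("config must be a mapping with a `mode` key")
  if (!(config$mode %in% experiment_modes))
    fail_config("mode must be one of: %s",
                paste(experiment_modes, collapse = ", "))
  allowed <- c(config_schema$common, config_schema[[config$mode]])
  check_keys(config, allowed, "config")
  for (key in names(config_defaults))
    if (key %in% names(allowed) && is.null(config[[key]]))
      config[[key]] <- config_defaults[[key]]
  check_number(config$seed, "seed")

  ## mode-specific deep validation (constructors throw on bad values)
  switch(config$mode,
    "simulate-sde" = {
      config_rate(config$model)
      config_initial(config$initial)
      check_keys(config$grid, c(t_start = FALSE, t_end = TRUE, n_steps = TRUE),
                 "grid")
      simulation_grid(config$grid$t_end, config$grid$n_steps,
                      t_start = config$grid$t_start %||% 0)
      check_count(config$n_paths, "n_paths")
      if (!(config$scheme %in% c("exact", "euler-maruyama")))
        fail_config("scheme must be 'exact' or 'euler-maruyama'")
      if (!(config$format %in% c("wide", "long")))
        fail_config("format must be 'wide' or 'long'")
    },
    "solve-fpe" = {
      config_rate(config$model)
      config_initial(config$initial)
      check_keys(config$fpe, c(t_final = TRUE, n_grid = FALSE,
                               n_steps = FALSE, width_sd = FALSE), "fpe")
    },
    "sample-mechanism" = {
      mech <- config$mechanism
      check_keys(mech, c(kind = TRUE, n = TRUE, params = FALSE,
                         components = FALSE, weights = FALSE,
                         persistence = FALSE, mode = FALSE,
                         oscillation = FALSE), "mechanism")
      if (!(mech$kind %in% c("kinetic", "mixture", "convolution",
                             "oscillatory")))
        fail_config("mechanism.kind must be kinetic|mixture|convolution|oscillatory")
      check_count(mech$n, "mechanism.n")
    },
    "analyze" = ,
    "recover" = {
      if (!is.character(config$input))
        fail_config("input must be a file path")
      if (!(config$dialect %in% c("single-column", "wide", "long")))
        fail_config("dialect must be single-column|wide|long")
    }
  )
  structure(config, class = c("experiment_config", "list"))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

provenance <- function(config) {
  list(config_hash = config_hash(config),
       seed = config$seed,
       package = "lognormkin",
       version = as.character(utils::packageVersion("lognormkin")))
}

#' Write an ensemble to CSV
#'
#' Wide format: first column `time`, remaining columns `path_0001`, ...;
#' long format: columns `time`, `path_id`, `concentration`.  A JSON sidecar
#' (`<path>.meta.json`) records the rate model, scheme, seed and provenance.
#'
#' @param ensemble An `ensemble_trajectories`.
#' @param path Output CSV path.
#' @param format `"wide"` (default) or `"long"`.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path, format = c("wide", "long"),
                               sidecar = TRUE) {
  stopifnot(inherits(ensemble, "ensemble_trajectories"))
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(time = ensemble$times,
                     t(ensemble$paths), check.names = FALSE)
    names(df)[-1] <- sprintf("path_%04d", seq_len(nrow(ensemble$paths)))
  } else {
    df <- as.data.frame(ensemble)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(
      scheme = ensemble$scheme,
      rate = ensemble$rate[c("mu_k", "sigma_k", "direction")],
      initial = unclass(ensemble$initial),
      seed = ensemble$noise$seed,
      n_paths = nrow(ensemble$paths),
      times = ensemble$times,
      format = format,
      package = "lognormkin",
      version = as.character(utils::packageVersion("lognormkin"))
    )
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a concentration table
#'
#' Parses concentration data in one of three CSV dialects, with strict
#' positivity validation and explicit errors for non-numeric cells:
#' * `"single-column"`: one concentration column (first column; an optional
#'   `time` column is ignored for sample-based diagnostics) -- returns a
#'   numeric vector;
#' * `"wide"`: `time, path_0001, ...` -- returns an
#'   `ensemble_trajectories`;
#' * `"long"`: `time, path_id, concentration` -- returns an
#'   `ensemble_trajectories`.
#'
#' @param path CSV path.
#' @param dialect One of `"single-column"`, `"wide"`, `"long"`.
#' @param rate Optional [rate_model()] attached to a parsed ensemble (so
#'   [recover_kinetics()] knows the process direction); default sink with
#'   unknown magnitudes.
#' @return Numeric vector or `ensemble_trajectories`, per dialect.
#' @export
read_concentration_table <- function(path,
                                     dialect = c("single-column", "wide", "long"),
                                     rate = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop(sprintf("empty input: %s has no data rows", path), call. = FALSE)

  numeric_col <- function(col, name) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric cells in column '%s' at data rows: %s",
                     name, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
      v <- vn
    }
    v
  }

  if (dialect == "single-column") {
    col <- setdiff(names(df), "time")[1]
    x <- numeric_col(col, col)
    assert_positive_samples(x, sprintf("column '%s' of %s", col, path))
    return(x)
  }

  rate <- rate %||% rate_model(mu_k = 0, sigma_k = 0)
  if (dialect == "wide") {
    if (names(df)[1] != "time")
      stop("wide dialect requires a leading 'time' column", call. = FALSE)
    times <- numeric_col("time", "time")
    paths <- t(as.matrix(vapply(names(df)[-1],
                                function(nm) numeric_col(nm, nm),
                                numeric(nrow(df)))))
    assert_positive_samples(as.vector(paths), sprintf("paths in %s", path))
    return(new_ensemble(times, paths, rate, noise_spec(0L), "file",
                        lognormal_params(0, 0)))
  }

  ## long
  need <- c("time", "path_id", "concentration")
  if (!all(need %in% names(df)))
    stop("long dialect requires columns time, path_id, concentration",
         call. = FALSE)
  times <- sort(unique(numeric_col("time", "time")))
  conc <- numeric_col("concentration", "concentration")
  assert_positive_samples(conc, sprintf("concentration in %s", path))
  ids <- sort(unique(df$path_id))
  paths <- matrix(NA_real_, length(ids), length(times))
  ti <- match(df$time, times)
  pi <- match(df$path_id, ids)
  paths[cbind(pi, ti)] <- conc
  if (anyNA(paths))
    stop("long input is not a complete (time x path) grid", call. = FALSE)
  new_ensemble(times, paths, rate, noise_spec(0L), "file",
               lognormal_params(0, 0))
}

#' Run a configured experiment
#'
#' Validates the config, derives the module sub-seed from the global seed
#' (see [derive_seed()]), dispatches to the relevant module, writes the
#' outputs plus the resolved config and a structured JSON run log (parameters,
#' seed, runtime, warnings) into `out_dir`, and returns the artifact paths
#' with a result summary.
#'
#' @param config An `experiment_config`, a named list, or a YAML file path.
#' @param out_dir Output directory override (default: the config's
#'   `out_dir`).
#' @return Invisibly, a list with `outputs` (paths), `summary` (mode-specific
#'   result object) and `log` (the run-log path).
#' @examples
#' cfg <- list(mode = "sample-mechanism", seed = 1,
#'             mechanism = list(kind = "kinetic", n = 100,
#'                              params = list(mu = 0, sigma2 = 1)))
#' out <- run_experiment(cfg, out_dir = tempdir())
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  config <- validate_experiment_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  warn <- character()
  res <- withCallingHandlers(
    dispatch_experiment(config),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  resolved_path <- file.path(config$out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), resolved_path)
  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(
    c(provenance(config),
      list(mode = config$mode, runtime_s = proc.time()[["elapsed"]] - t0,
           warnings = warn, outputs = unname(unlist(res$outputs)))),
    log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(config$verbose))
    message(sprintf("[lognormkin] %s done in %.2fs; outputs in %s",
                    config$mode, proc.time()[["elapsed"]] - t0, config$out_dir))
  invisible(list(outputs = c(res$outputs,
                             list(resolved_config = resolved_path)),
                 summary = res$summary, log = log_path))
}

dispatch_experiment <- function(config) {
  out <- config$out_dir
  switch(config$mode,
    "simulate-sde" = {
      rate <- config_rate(config$model)
      init <- config_initial(config$initial)
      grid <- simulation_grid(config$grid$t_end, config$grid$n_steps,
                              t_start = config$grid$t_start %||% 0)
      noise <- noise_spec(derive_seed(config$seed, "sde"))
      ens <- if (config$scheme == "exact")
        simulate_exact(init, rate, grid, config$n_paths, noise)
      else
        simulate_euler_maruyama(init, rate, grid, config$n_paths, noise)
      path <- file.path(out, "ensemble.csv")
      write_ensemble_csv(ens, path, format = config$format)
      list(outputs = list(ensemble = path,
                          sidecar = paste0(path, ".meta.json")),
           summary = ens)
    },
    "solve-fpe" = {
      rate <- config_rate(config$model)
      init <- config_initial(config$initial)
      fp <- config$fpe
      sol <- fpe_evolve(init, rate, fp$t_final,
                        n_grid = fp$n_grid %||% 2048,
                        n_steps = fp$n_steps %||% 1000,
                        width_sd = fp$width_sd %||% 8)
      path <- file.path(out, "density.csv")
      utils::write.csv(data.frame(log_concentration = sol$density$y,
                                  density = sol$density$values),
                       path, row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        c(list(time = sol$density$time,
               analytic = unclass(sol$analytic)), sol$error,
          provenance(config)),
        paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      list(outputs = list(density = path,
                          sidecar = paste0(path, ".meta.json")),
           summary = sol)
    },
    "sample-mechanism" = {
      mech <- config$mechanism
      noise <- noise_spec(derive_seed(config$seed, "mechanism"))
      n <- mech$n
      res <- switch(mech$kind,
        kinetic = {
          p <- config_initial(mech$params)
          data.frame(concentration = sample_kinetic(p, n, noise))
        },
        mixture = {
          sp <- mixture_spec(config_lognormal_list(mech$components,
                                                   "mechanism.components"),
                             weights = mech$weights,
                             persistence = mech$persistence)
          o <- sample_mixture(sp, n, noise, mode = mech$mode %||% "iid")
          data.frame(concentration = o$samples, state = o$states)
        },
        convolution = {
          sp <- mixture_spec(config_lognormal_list(mech$components,
                                                   "mechanism.components"))
          data.frame(concentration = sample_convolution(sp, n, noise))
        },
        oscillatory = {
          p <- config_initial(mech$params)
          oc <- mech$oscillation
          check_keys(oc, c(amplitude = TRUE, period = TRUE, phase = FALSE),
                     "mechanism.oscillation")
          o <- sample_oscillatory(p, oscillation_spec(oc$amplitude, oc$period,
                                                      oc$phase %||% 0),
                                  n, noise)
          data.frame(time = o$times, concentration = o$samples)
        })
      path <- file.path(out, "samples.csv")
      utils::write.csv(res, path, row.names = FALSE, quote = FALSE)
      jsonlite::write_json(c(list(kind = mech$kind, n = n),
                             provenance(config)),
                           paste0(path, ".meta.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(outputs = list(samples = path,
                          sidecar = paste0(path, ".meta.json")),
           summary = res)
    },
    "analyze" = {
      x <- read_concentration_table(config$input, config$dialect)
      if (inherits(x, "ensemble_trajectories")) x <- as.vector(x$paths)
      fit <- fit_lognormal(x)
      ht <- test_lognormality(x, alpha = config$alpha,
                              method = config$method,
                              subsample_seed = derive_seed(config$seed,
                                                           "analyze"))
      path <- file.path(out, "fit_report.json")
      jsonlite::write_json(c(unclass(fit),
                             list(normality_test = unclass(ht)),
                             provenance(config)),
                           path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      list(outputs = list(fit_report = path),
           summary = list(fit = fit, test = ht))
    },
    "recover" = {
      rate <- if (!is.null(config$model)) config_rate(config$model) else NULL
      ens <- read_concentration_table(config$input, config$dialect,
                                      rate = rate)
      if (!inherits(ens, "ensemble_trajectories"))
        fail_config("recover mode needs a wide or long ensemble input")
      rec <- recover_kinetics(ens, n_boot = config$n_boot,
                              boot_seed = derive_seed(config$seed, "recover"))
      path <- file.path(out, "kinetic_recovery.json")
      jsonlite::write_json(c(rec[c("mu_k_hat", "sigma_k2_hat",
                                   "sigma_k2_clipped", "slope_mean",
                                   "slope_var", "n_paths", "n_times",
                                   "direction")],
                             list(ci = rec$ci), provenance(config)),
                           path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      list(outputs = list(kinetic_recovery = path), summary = rec)
    }
  )
}
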