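#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: where the data come from
#' (a [synthetic_scenario()] or CSV paths), which streams and discharge
#' seasons to use, and the per-stage settings.
#'
#' @param scenario A [synthetic_scenario()], or \code{NULL} when reading
#'   CSVs.
#' @param paths When \code{scenario} is NULL: list with \code{discharge}
#'   (named character vector, one CSV per stream), \code{temperature},
#'   \code{limno}.
#' @param streams Stream ids to analyse.
#' @param seasons Integer discharge season labels (default: the scenario's).
#' @param variables Response variables to fit.
#' @param zeta Log-transform offset.
#' @param depth_cutoff Chemocline cutoff in metres.
#' @param basis_family,K Basis settings for the regression stage.
#' @param lambda Fixed ridge penalty, or \code{NULL} for per-stream LOOCV
#'   selection over \code{lambdas}.
#' @param lambdas Candidate penalty grid.
#' @param covariate_scale \code{"log"} or \code{"linear"} discharge curves.
#' @param gmrf List of imputation settings: \code{method} ("gibbs" or
#'   "exact"), \code{n_draws}, \code{burn_in}, \code{order}, \code{l_min},
#'   \code{exact_sigma_e2} (observation variance used by the fixed-
#'   hyperparameter "exact" method).
#' @param seed Global seed, expanded deterministically per stage and pair.
#' @param outdir Optional directory for stage artifacts and summary JSON.
#' @return A validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(scenario = NULL, paths = NULL,
                            streams = if (!is.null(scenario))
                              scenario$streams else names(paths$discharge),
                            seasons = if (!is.null(scenario))
                              scenario$first_season +
                                seq_len(scenario$n_seasons) - 1L
                              else stop("seasons required with paths"),
                            variables = c("ppr", "chl"),
                            zeta = 0.01, depth_cutoff = 11,
                            basis_family = "fourier", K = 5,
                            lambda = NULL,
                            lambdas = default_lambda_grid(),
                            covariate_scale = "log",
                            gmrf = list(), seed = 1, outdir = NULL) {
  gmrf <- utils::modifyList(
    list(method = "gibbs", n_draws = 2000, burn_in = 1000, order = 1,
         l_min = 5, exact_sigma_e2 = 1e-8),
    gmrf)
  if (is.null(scenario) && is.null(paths))
    stop("either a scenario or input paths must be given")
  if (length(streams) == 0) stop("stream set is empty")
  if (length(seasons) == 0) stop("season range is empty")
  if (!is.null(scenario) && !all(streams %in% scenario$streams))
    stop("unknown stream id(s): ",
         paste(setdiff(streams, scenario$streams), collapse = ", "))
  if (is.null(scenario)) {
    if (!all(streams %in% names(paths$discharge)))
      stop("unknown stream id(s): ",
           paste(setdiff(streams, names(paths$discharge)), collapse = ", "))
    for (p in c(paths$discharge[streams], paths$temperature, paths$limno))
      if (!file.exists(p)) stop("input not found: ", p)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# stage 1: assemble the observation bundle either from the generator or
# from CSV files
ingest_bundle <- function(config) {
  grids <- stats::setNames(lapply(config$seasons, season_grid),
                           as.character(config$seasons))
  if (!is.null(config$scenario)) {
    ds <- gen_dataset(config$scenario)
    keep <- as.vector(outer(config$streams, config$seasons, paste,
                            sep = "|"))
    return(list(grids = grids[as.character(config$seasons)],
                temps = ds$temps[as.character(config$seasons)],
                obs = ds$obs[intersect(keep, names(ds$obs))],
                profiles = ds$profiles,
                truths = ds$truths, true_responses = ds$responses))
  }
  temps <- obs <- list()
  for (key in names(grids))
    temps[[key]] <- read_temperature(config$paths$temperature, grids[[key]])
  for (st in config$streams) {
    recs <- read_discharge(config$paths$discharge[[st]], st)
    for (key in names(grids)) {
      da <- daily_average(recs, grids[[key]])
      obs[[paste(st, key, sep = "|")]] <-
        log_transform(da, grids[[key]], stream_id = st, zeta = config$zeta)
    }
  }
  list(grids = grids, temps = temps, obs = obs,
       profiles = read_limno_profiles(config$paths$limno))
}

# stage 2: gap-fill every stream-season
impute_stage <- function(bundle, config) {
  g <- config$gmrf
  if (g$method == "gibbs")
    return(impute_all(bundle, config$streams, config$seasons,
                      seed = config$seed, n_draws = g$n_draws,
                      burn_in = g$burn_in, order = g$order,
                      l_min = g$l_min))
  # fixed-hyperparameter conditioning: temperature regression plug-in
  out <- list()
  for (key in names(bundle$obs)) {
    ob <- bundle$obs[[key]]
    skey <- as.character(ob$season_label)
    temp <- bundle$temps[[skey]]
    grid <- bundle$grids[[skey]]
    if (ob$L < g$l_min) { message("skipping ", key, ": L < l_min"); next }
    W <- cbind(1, temp$values[ob$obs_idx])
    cf <- stats::lm.fit(W, ob$values)$coefficients
    cf[is.na(cf)] <- 0
    out[[key]] <- conditional_latent(
      ob, temp,
      hyper = list(delta0 = cf[1], delta1 = cf[2],
                   sigma_e2 = g$exact_sigma_e2),
      prec = rw_precision(grid, tau = 1, order = g$order))
  }
  attr(out, "absent") <- data.frame()
  out
}

#' Run the full discharge-to-biology pipeline
#'
#' Ingest (or generate) the data, gap-fill every stream-season discharge
#' record, aggregate the limnological profiles into lag-one seasonal
#' responses, fit the per-stream scalar-on-function models, and average
#' their predictions. Identical configuration and seed give an identical
#' summary.
#'
#' @param config A [pipeline_config()].
#' @return Object of class \code{"hydro_pipeline"}: \code{latents},
#'   \code{designs}, \code{fits}, \code{ensembles} (per variable), and
#'   \code{summary} (per-variable per-model and averaged R-squared,
#'   predictions with 2-SE bands, chosen penalties, seed and config hash).
#'   When \code{config$outdir} is set, stage artifacts (latent curves,
#'   predictions, coefficient curves as CSV; summary as JSON) are written
#'   there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- ingest_bundle(config)
  latents <- impute_stage(bundle, config)
  grid1 <- bundle$grids[[1]]
  basis <- make_basis(config$basis_family, config$K, grid1)

  designs <- fits <- ensembles <- list()
  for (v in config$variables) {
    resp <- list()
    for (s in config$seasons + 1L) {
      r <- tryCatch(
        seasonal_response(bundle$profiles, v, s, config$depth_cutoff),
        error = function(e) NULL)
      if (is.null(r)) message("no ", v, " response for season ", s)
      else resp[[as.character(s)]] <- r
    }
    designs[[v]] <- build_lagged_design(resp, latents, config$streams)
    fits[[v]] <- fit_per_stream_models(
      designs[[v]], basis, lambda = config$lambda,
      covariate_scale = config$covariate_scale, lambdas = config$lambdas)
    ensembles[[v]] <- ensemble_predict(fits[[v]])
  }

  summary <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    basis = list(family = config$basis_family, K = config$K),
    covariate_scale = config$covariate_scale,
    variables = lapply(stats::setNames(nm = config$variables), function(v)
      list(r2_per_model = as.list(ensembles[[v]]$r2),
           r2_avg = ensembles[[v]]$r2_avg,
           lambda = lapply(fits[[v]], `[[`, "lambda"),
           n = length(designs[[v]]),
           predictions = ensembles[[v]]$predictions)))
  out <- structure(
    list(bundle = bundle, latents = latents, basis = basis,
         designs = designs, fits = fits, ensembles = ensembles,
         summary = summary, config = config),
    class = "hydro_pipeline")
  if (!is.null(config$outdir)) write_artifacts(out, config$outdir)
  out
}

#' @export
print.hydro_pipeline <- function(x, ...) {
  cat("Discharge-to-biology pipeline run\n")
  cat(sprintf("  %d stream(s) x %d discharge season(s); basis %s K = %d; %s scale\n",
              length(x$config$streams), length(x$config$seasons),
              x$config$basis_family, x$config$K, x$config$covariate_scale))
  for (v in names(x$ensembles))
    cat(sprintf("  %s: averaged R-squared %.2f%% over %d seasons\n",
                toupper(v), 100 * x$ensembles[[v]]$r2_avg,
                nrow(x$ensembles[[v]]$predictions)))
  invisible(x)
}

config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "outdir")]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

write_artifacts <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lat <- do.call(rbind, lapply(names(run$latents), function(key) {
    l <- run$latents[[key]]
    g <- run$bundle$grids[[as.character(l$season_label)]]
    data.frame(stream = l$stream_id, season = l$season_label, t = g$t,
               mean = l$mean, sd = l$sd)
  }))
  utils::write.csv(lat, file.path(outdir, "latent_discharge.csv"),
                   row.names = FALSE)
  for (v in names(run$ensembles)) {
    utils::write.csv(run$ensembles[[v]]$predictions,
                     file.path(outdir, paste0("predictions_", v, ".csv")),
                     row.names = FALSE)
    B <- do.call(cbind, lapply(run$fits[[v]], reconstruct_beta))
    utils::write.csv(
      data.frame(t = run$basis$grid$t, B, check.names = FALSE),
      file.path(outdir, paste0("beta_", v, ".csv")), row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(run$summary,
                         file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Sweep basis size, penalty and covariate scale
#'
#' Re-runs the regression stage over a grid of settings while computing the
#' imputation stage once (the gap-filling does not depend on basis or
#' penalty). Returns the averaged R-squared per setting and variable.
#'
#' @param config A [pipeline_config()]; its own K / scale settings are
#'   ignored in favour of the grids below.
#' @param K_values Basis sizes to try.
#' @param covariate_scales Covariate scales to try.
#' @param lambda As in [pipeline_config()] (\code{NULL} = LOOCV per
#'   stream).
#' @return Data frame with one row per setting: \code{K},
#'   \code{covariate_scale}, and \code{r2_<variable>} columns (averaged
#'   R-squared, in percent).
#' @export
sweep_pipeline <- function(config, K_values = c(3, 5, 7),
                           covariate_scales = c("log", "linear"),
                           lambda = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- ingest_bundle(config)
  latents <- impute_stage(bundle, config)
  grid1 <- bundle$grids[[1]]

  resp <- list()
  for (v in config$variables) {
    resp[[v]] <- list()
    for (s in config$seasons + 1L) {
      r <- tryCatch(
        seasonal_response(bundle$profiles, v, s, config$depth_cutoff),
        error = function(e) NULL)
      if (!is.null(r)) resp[[v]][[as.character(s)]] <- r
    }
  }

  rows <- list()
  for (K in K_values) for (cs in covariate_scales) {
    basis <- make_basis(config$basis_family, K, grid1)
    row <- list(K = K, covariate_scale = cs)
    for (v in config$variables) {
      design <- build_lagged_design(resp[[v]], latents, config$streams)
      fits <- fit_per_stream_models(design, basis, lambda = lambda,
                                    covariate_scale = cs,
                                    lambdas = config$lambdas)
      row[[paste0("r2_", v)]] <- 100 * ensemble_predict(fits)$r2_avg
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}
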