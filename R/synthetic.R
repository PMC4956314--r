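# Seeded synthetic data with the statistical structure the pipeline assumes:
# seasonal air temperature, log-discharge linearly coupled to temperature
# plus AR(1) deviations (deliberately not the RW fitting prior, so the
# imputation stage faces mild misspecification), contiguous observation
# gaps, zero-flow floors, and seasonal responses generated from a known
# functional coefficient.

# deterministic sub-seed expansion: one global seed, independent substreams
# per stage/stream/season so adding a stream leaves the others' draws alone
sub_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (p in parts) s <- (s * 69069 + as.double(abs(sum(utf8ToInt(
    as.character(p)))))) %% 2147483647
  as.integer(s)
}

#' Synthetic study scenario
#'
#' Bundles every knob of the generator. The defaults mirror the scale of
#' the field study: 17 discharge seasons starting in 1994, three streams,
#' a 62-node daily December--January grid, temperature-linked latent
#' log-discharge with AR(1) deviations, observation gaps of a few days to
#' three weeks, and responses whose signal-to-noise ratio is 3:1 unless a
#' noise sd is given explicitly.
#'
#' @param seed Global integer seed; all generators derive substreams from it.
#' @param n_seasons Number of discharge seasons.
#' @param streams Stream identifiers.
#' @param first_season Calendar year of the first discharge season.
#' @param delta0,delta1 True temperature-link coefficients of the latent
#'   log-discharge mean.
#' @param ar_rho,ar_sigma AR(1) autocorrelation and innovation sd of the
#'   latent deviations (|ar_rho| < 1).
#' @param sigma_e Observation noise sd on the log scale.
#' @param gap_spec List: either \code{n_gaps}, \code{min_len},
#'   \code{max_len} for random contiguous gaps, or explicit \code{starts}
#'   and \code{lengths} (1-based node indices).
#' @param k_true Number of Fourier terms defining the true coefficient
#'   curves.
#' @param gamma_true True basis coefficients of beta(t), recycled across
#'   streams (length \code{k_true}).
#' @param alpha_true True intercepts, one per response variable.
#' @param gamma_scale Per-variable multiplier on \code{gamma_true}.
#' @param gamma_stream_scale Per-stream multiplier on \code{gamma_true}
#'   (recycled; lets one stream carry all the signal).
#' @param response_sigma Per-variable response noise sd; \code{NULL} means
#'   "set from the realized signal sd at \code{snr}".
#' @param snr Signal-to-noise ratio used when \code{response_sigma} is NULL.
#' @param profile_sd Sampling noise of individual depth-profile values.
#' @param below_offset Shift added to values below the chemocline so the
#'   depth filter is exercised.
#' @param zeta Offset of the log transform.
#' @return A list of class \code{"hydro_scenario"}.
#' @export
synthetic_scenario <- function(seed = 1,
                               n_seasons = 17,
                               streams = c("canada", "lost_seal",
                                           "von_guerard"),
                               first_season = 1994,
                               delta0 = -2, delta1 = 0.8,
                               ar_rho = 0.85, ar_sigma = 0.5,
                               sigma_e = 0.3,
                               gap_spec = list(n_gaps = 2, min_len = 3,
                                               max_len = 21),
                               k_true = 3,
                               gamma_true = c(-0.25, 0.12, 0.18),
                               alpha_true = c(ppr = 12, chl = 4),
                               gamma_scale = c(ppr = 1, chl = 0.35),
                               gamma_stream_scale = 1,
                               response_sigma = NULL,
                               snr = 3,
                               profile_sd = 0.5,
                               below_offset = 6,
                               zeta = 0.01) {
  stopifnot(abs(ar_rho) < 1, ar_sigma > 0, sigma_e >= 0, zeta > 0,
            length(gamma_true) == k_true, n_seasons >= 1)
  structure(as.list(environment()), class = "hydro_scenario")
}

#' @export
print.hydro_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d seasons from %d, streams %s, seed %d\n",
    x$n_seasons, x$first_season, paste(x$streams, collapse = "/"), x$seed))
  invisible(x)
}

#' Generate a season of daily air temperature
#'
#' Deterministic seasonal curve peaking around the turn of the year (late
#' December / early January) plus day-to-day Gaussian noise, spanning a
#' plausible Antarctic summer range of roughly -10 to +5 degrees C.
#'
#' @param scenario A [synthetic_scenario()].
#' @param season Season label (December's calendar year).
#' @param noise_sd Day-to-day noise sd; 0 gives the pure curve.
#' @return A \code{temperature_series} on [season_grid()]\code{(season)}.
#' @export
gen_temperature <- function(scenario, season, noise_sd = 1.2) {
  grid <- season_grid(season)
  set.seed(sub_seed(scenario$seed, "temp", season))
  curve <- -7 + 9 * exp(-0.5 * ((grid$t - 30) / 16)^2)
  vals <- curve + stats::rnorm(length(curve), 0, noise_sd)
  structure(list(season_label = season, values = vals, n_filled = 0L),
            class = "temperature_series")
}

# realize the gap mask (TRUE = observed) for one stream-season
gap_mask <- function(gap_spec, n_nodes) {
  obs <- rep(TRUE, n_nodes)
  if (!is.null(gap_spec$starts)) {
    for (g in seq_along(gap_spec$starts)) {
      idx <- gap_spec$starts[g] + seq_len(gap_spec$lengths[g]) - 1L
      obs[idx[idx <= n_nodes]] <- FALSE
    }
  } else if (!is.null(gap_spec$n_gaps) && gap_spec$n_gaps > 0) {
    for (g in seq_len(gap_spec$n_gaps)) {
      len <- sample(gap_spec$min_len:gap_spec$max_len, 1)
      start <- sample(seq_len(max(n_nodes - len, 1)), 1)
      obs[start + seq_len(len) - 1L] <- FALSE
    }
  }
  if (!any(obs)) obs[1] <- TRUE   # gaps must never cover every node
  obs
}

#' Generate one stream-season of latent and observed log-discharge
#'
#' Latent truth: \code{DR(t) = delta0 + delta1*T(t) + u(t)} with AR(1)
#' deviations \code{u}, floored at \code{log(zeta)} so the implied
#' discharge \code{exp(DR) - zeta} is never negative (cold spells produce
#' genuine zero-flow intervals). Observations add iid Gaussian noise on the
#' log scale (also floored -- a gauge cannot read negative flow) and are
#' masked in contiguous blocks per \code{gap_spec}.
#'
#' @param scenario A [synthetic_scenario()].
#' @param temp A \code{temperature_series} for the season.
#' @param stream_id Stream identifier (seeds the substream).
#' @return List with \code{truth} (latent DR at every node), \code{obs}
#'   (a \code{log_discharge_obs}), and \code{grid}.
#' @export
gen_discharge <- function(scenario, temp, stream_id = "stream1") {
  season <- temp$season_label
  grid <- season_grid(season)
  n <- grid$M + 1L
  set.seed(sub_seed(scenario$seed, "disch", stream_id, season))
  u <- numeric(n)
  u[1] <- stats::rnorm(1, 0, scenario$ar_sigma /
                            sqrt(1 - scenario$ar_rho^2))
  innov <- stats::rnorm(n - 1, 0, scenario$ar_sigma)
  for (m in 2:n) u[m] <- scenario$ar_rho * u[m - 1] + innov[m - 1]
  # deviations are within-season fluctuations around the temperature-driven
  # mean: centred so delta0 is the season's level by definition (a single
  # season cannot separate the intercept from the deviations' mean)
  u <- u - mean(u)
  truth <- pmax(scenario$delta0 + scenario$delta1 * temp$values + u,
                log(scenario$zeta))
  noise <- if (scenario$sigma_e > 0)
    stats::rnorm(n, 0, scenario$sigma_e) else numeric(n)
  obs_vals <- pmax(truth + noise, log(scenario$zeta))
  observed <- gap_mask(scenario$gap_spec, n)
  oi <- which(observed)
  obs <- structure(
    list(stream_id = stream_id, season_label = season,
         obs_idx = oi, obs_times = grid$t[oi], values = obs_vals[oi],
         L = length(oi), zeta = scenario$zeta),
    class = "log_discharge_obs")
  list(truth = truth, obs = obs, grid = grid)
}

# true coefficient curves: k_true-term Fourier expansion, one curve per
# stream (gamma recycled, scaled per variable)
true_beta_basis <- function(scenario, grid = season_grid(2000)) {
  make_basis("fourier", scenario$k_true, grid)
}

#' Generate seasonal responses from the true functional coefficient
#'
#' \code{Y_s = alpha + sum_j quad(beta_true_j, X_{s-1,j}) + noise}: the
#' response of season \code{s} integrates the true latent discharge curves
#' of the previous season (the lag-one convention of the pipeline) against
#' the true coefficient curves, by the same left-Riemann quadrature the
#' fitting stage uses.
#'
#' @param scenario A [synthetic_scenario()].
#' @param truths Named list (season label as name) of named lists (stream
#'   -> latent truth vector), as accumulated from [gen_discharge()].
#' @param variable \code{"ppr"} or \code{"chl"}.
#' @return Data frame (season, y, signal) with one row per response season
#'   (discharge season + 1); attribute \code{"response_sigma"} records the
#'   noise sd actually used.
#' @export
gen_responses <- function(scenario, truths, variable = c("ppr", "chl")) {
  variable <- match.arg(variable)
  seasons <- as.integer(names(truths))
  basis <- true_beta_basis(scenario, season_grid(seasons[1]))
  gam <- scenario$gamma_true * scenario$gamma_scale[[variable]]
  ssc <- rep_len(scenario$gamma_stream_scale, length(scenario$streams))
  signal <- vapply(truths, function(per_stream) {
    sum(vapply(seq_along(scenario$streams), function(j)
      ssc[j] * sum(quadrature_scores(
        matrix(per_stream[[scenario$streams[j]]], 1), basis) * gam),
      numeric(1)))
  }, numeric(1))
  sig_sd <- stats::sd(signal)
  rs <- scenario$response_sigma[[variable]] %||%
    (if (sig_sd > 0) sig_sd / scenario$snr else 0)
  set.seed(sub_seed(scenario$seed, "resp", variable))
  y <- scenario$alpha_true[[variable]] + signal +
    stats::rnorm(length(signal), 0, rs)
  structure(
    data.frame(season = seasons + 1L, y = y,
               signal = scenario$alpha_true[[variable]] + signal),
    response_sigma = rs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate depth profiles realizing the seasonal responses
#'
#' Per response season: 3--4 sampling dates in October--December, depths
#' 0.5 m to 18 m in half-metre steps. Values at depths above the chemocline
#' cutoff are centred on the season's response (so aggregation recovers it
#' in expectation); deeper values are shifted by \code{below_offset} so the
#' depth filter is genuinely exercised. Values are truncated at zero, as
#' concentrations must be.
#'
#' @param scenario A [synthetic_scenario()].
#' @param responses Named list of [gen_responses()] frames, one per
#'   variable (\code{ppr}, \code{chl}).
#' @param depth_cutoff Chemocline depth (m) separating the two regimes.
#' @return A \code{limno_profiles} data frame with both variables.
#' @export
gen_limno_profiles <- function(scenario, responses, depth_cutoff = 11) {
  depths <- seq(0.5, 18, by = 0.5)
  rows <- list()
  seasons <- responses[[1]]$season
  for (s in seasons) {
    set.seed(sub_seed(scenario$seed, "limno", s))
    n_dates <- sample(3:4, 1)
    dates <- as.Date(sprintf("%d-10-01", s)) +
      sort(sample(0:90, n_dates))
    for (d in dates) {
      above <- depths <= depth_cutoff
      vals <- lapply(names(responses), function(v) {
        y <- responses[[v]]$y[responses[[v]]$season == s]
        mu <- ifelse(above, y, y + scenario$below_offset)
        pmax(mu + stats::rnorm(length(depths), 0, scenario$profile_sd), 0)
      })
      names(vals) <- names(responses)
      rows[[length(rows) + 1L]] <- data.frame(
        date = as.Date(d, origin = "1970-01-01"), depth_m = depths,
        ppr = vals$ppr %||% NA_real_, chl = vals$chl %||% NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("limno_profiles", "data.frame")
  out
}

#' Generate the full synthetic data bundle
#'
#' Runs every generator over all streams and seasons and returns the
#' in-memory bundle the pipeline stages consume, plus the ground truth
#' needed by recovery tests.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List: \code{grids}, \code{temps} (by season), \code{obs} (by
#'   \code{"<stream>|<season>"}), \code{truths} (by season, then stream),
#'   \code{responses} (list by variable), \code{profiles}, \code{scenario}.
#' @export
gen_dataset <- function(scenario) {
  seasons <- scenario$first_season + seq_len(scenario$n_seasons) - 1L
  grids <- temps <- list()
  obs <- list()
  truths <- list()
  for (s in seasons) {
    key <- as.character(s)
    temps[[key]] <- gen_temperature(scenario, s)
    grids[[key]] <- season_grid(s)
    truths[[key]] <- list()
    for (st in scenario$streams) {
      g <- gen_discharge(scenario, temps[[key]], st)
      obs[[paste(st, s, sep = "|")]] <- g$obs
      truths[[key]][[st]] <- g$truth
    }
  }
  responses <- list(ppr = gen_responses(scenario, truths, "ppr"),
                    chl = gen_responses(scenario, truths, "chl"))
  profiles <- gen_limno_profiles(scenario, responses)
  list(grids = grids, temps = temps, obs = obs, truths = truths,
       responses = responses, profiles = profiles, scenario = scenario)
}

#' Write a synthetic dataset as the CSV dialects the readers expect
#'
#' One discharge CSV per stream (two sub-daily rows per observed day so
#' daily averaging is exercised), one temperature CSV covering all season
#' grids, one limnological profile CSV.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of file paths (\code{discharge} named by stream,
#'   \code{temperature}, \code{limno}).
#' @export
write_synthetic_dataset <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen_dataset(scenario)
  paths <- list(discharge = character(0))
  for (st in scenario$streams) {
    rows <- list()
    for (key in names(ds$grids)) {
      ob <- ds$obs[[paste(st, key, sep = "|")]]
      dates <- ds$grids[[key]]$dates[ob$obs_idx]
      q <- pmax(exp(ob$values) - scenario$zeta, 0)
      rows[[key]] <- data.frame(
        timestamp = c(paste0(format(dates), "T06:00:00"),
                      paste0(format(dates), "T18:00:00")),
        discharge = rep(q, 2))
    }
    df <- do.call(rbind, rows)
    df <- df[order(df$timestamp), ]
    p <- file.path(dir, paste0("discharge_", st, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths$discharge[st] <- p
  }
  tdf <- do.call(rbind, lapply(names(ds$temps), function(key) data.frame(
    date = format(ds$grids[[key]]$dates),
    mean_temp_c = ds$temps[[key]]$values)))
  paths$temperature <- file.path(dir, "temperature.csv")
  utils::write.csv(tdf, paths$temperature, row.names = FALSE, quote = FALSE)
  ldf <- ds$profiles
  ldf$date <- format(ldf$date)
  paths$limno <- file.path(dir, "limno_profiles.csv")
  utils::write.csv(ldf, paths$limno, row.names = FALSE, quote = FALSE)
  invisible(paths)
}
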