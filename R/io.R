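#' Read a stream-discharge CSV
#'
#' Reads 15-minute (or coarser) volumetric discharge records for one stream.
#' The file must carry a header with \code{timestamp} (ISO-8601) and
#' \code{discharge} columns; an optional \code{flag} column is preserved.
#' Rows with unparseable or negative discharge are dropped with a message --
#' long historical gauge files routinely contain stray rows and should stay
#' usable. Missing data are absent rows, never sentinel values.
#'
#' @param path CSV file path.
#' @param stream_id Stream identifier attached to every record.
#' @return A data frame of class \code{"discharge_records"} with columns
#'   \code{stream_id}, \code{timestamp} (POSIXct, UTC storage of the literal
#'   clock time), \code{date} (calendar date as written in the file),
#'   \code{discharge}, and \code{flag} (NA when absent), sorted by timestamp.
#' @export
read_discharge <- function(path, stream_id) {
  if (!file.exists(path)) stop("discharge file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "discharge") %in% names(raw)))
    stop("discharge file lacks required columns 'timestamp', 'discharge': ",
         path)
  if (nrow(raw) == 0L) stop("discharge file has no data rows: ", path)
  disch <- suppressWarnings(as.numeric(raw$discharge))
  bad <- is.na(disch) | disch < 0
  if (any(bad))
    message(sum(bad), " discharge row(s) rejected (non-numeric or negative)")
  raw <- raw[!bad, , drop = FALSE]
  disch <- disch[!bad]
  if (nrow(raw) == 0L) stop("discharge file has no valid rows: ", path)
  ts <- as.POSIXct(sub("T", " ", raw$timestamp, fixed = TRUE), tz = "UTC")
  out <- data.frame(
    stream_id = stream_id,
    timestamp = ts,
    # day assignment uses the calendar date literally as written in the file
    date = as.Date(substr(as.character(raw$timestamp), 1, 10)),
    discharge = disch,
    flag = if ("flag" %in% names(raw)) as.character(raw$flag) else NA_character_,
    stringsAsFactors = FALSE)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("discharge_records", "data.frame")
  out
}

#' Write discharge records back to CSV
#'
#' Inverse of [read_discharge()]; used by the synthetic generator and for
#' round-trip checks.
#' @param records A \code{discharge_records} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_discharge_csv <- function(records, path) {
  df <- data.frame(
    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    discharge = records$discharge)
  if (!all(is.na(records$flag))) df$flag <- records$flag
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily-average discharge on a season grid
#'
#' Averages all records falling on each grid node's calendar day. Nodes
#' without any record are left missing -- imputation is the GMRF stage's job,
#' never done here.
#'
#' @param records A \code{discharge_records} data frame (may be empty).
#' @param grid A [season_grid()].
#' @return List with \code{value} (numeric, NA where unobserved) and
#'   \code{observed} (logical mask), both of length \code{grid$M + 1}.
#' @export
daily_average <- function(records, grid) {
  n_nodes <- grid$M + 1L
  value <- rep(NA_real_, n_nodes)
  if (NROW(records) > 0L) {
    idx <- grid_node_index(grid, records$date)
    keep <- !is.na(idx)
    if (any(keep)) {
      sums <- tapply(records$discharge[keep], idx[keep], mean)
      value[as.integer(names(sums))] <- as.numeric(sums)
    }
  }
  list(value = value, observed = !is.na(value))
}

#' Log-transform daily discharge into the observation set
#'
#' Applies \code{DR = log(zeta + discharge)} at every observed node. The
#' positive offset \code{zeta} keeps zero-flow days finite: a dry day maps to
#' \code{log(zeta)}, the floor of the transformed scale (\code{log(0.01)}
#' at the default).
#'
#' @param daily Output of [daily_average()].
#' @param grid The [season_grid()] the daily averages live on.
#' @param stream_id Stream identifier.
#' @param zeta Positive offset in the discharge units of the input file.
#' @return Object of class \code{"log_discharge_obs"}: \code{stream_id},
#'   \code{season_label}, \code{obs_idx} (1-based grid node indices),
#'   \code{obs_times}, \code{values}, \code{L}, \code{zeta}.
#' @export
log_transform <- function(daily, grid, stream_id = NA_character_, zeta = 0.01) {
  if (!is.numeric(zeta) || length(zeta) != 1 || zeta <= 0)
    stop("zeta must be a positive scalar")
  obs_idx <- which(daily$observed)
  structure(
    list(stream_id = stream_id,
         season_label = grid$season_label,
         obs_idx = obs_idx,
         obs_times = grid$t[obs_idx],
         values = log(zeta + daily$value[obs_idx]),
         L = length(obs_idx),
         zeta = zeta),
    class = "log_discharge_obs")
}

#' Read daily mean air temperature onto a season grid
#'
#' Temperature drives the prior mean of the latent discharge process, so it
#' must be complete on the grid. Short interior gaps (at most
#' \code{max_gap_days} consecutive days) are filled by linear interpolation,
#' edge gaps of the same length by nearest-value extension; anything longer,
#' or more than \code{max_missing_frac} of nodes missing, aborts with an
#' insufficient-data error.
#'
#' @param path CSV with columns \code{date}, \code{mean_temp_c}.
#' @param grid A [season_grid()].
#' @param max_gap_days Longest gap (days) that may be filled.
#' @param max_missing_frac Maximum tolerated fraction of missing nodes.
#' @return Object of class \code{"temperature_series"}: \code{season_label},
#'   \code{values} (complete, one per node), \code{n_filled}.
#' @export
read_temperature <- function(path, grid, max_gap_days = 3,
                             max_missing_frac = 0.5) {
  if (!file.exists(path)) stop("temperature file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "mean_temp_c") %in% names(raw)))
    stop("temperature file lacks required columns 'date', 'mean_temp_c': ",
         path)
  idx <- grid_node_index(grid, raw$date)
  vals <- rep(NA_real_, grid$M + 1L)
  keep <- !is.na(idx) & !is.na(suppressWarnings(as.numeric(raw$mean_temp_c)))
  vals[idx[keep]] <- as.numeric(raw$mean_temp_c)[keep]
  temperature_from_values(vals, grid, max_gap_days, max_missing_frac)
}

# shared gap-filling core, also used on in-memory series
temperature_from_values <- function(vals, grid, max_gap_days = 3,
                                    max_missing_frac = 0.5) {
  miss <- is.na(vals)
  if (mean(miss) > max_missing_frac)
    stop("insufficient temperature data: ",
         round(100 * mean(miss)), "% of grid days missing")
  n_filled <- 0L
  if (any(miss)) {
    runs <- rle(miss)
    if (any(runs$lengths[runs$values] > max_gap_days))
      stop("insufficient temperature data: gap longer than ",
           max_gap_days, " days")
    filled <- stats::approx(grid$t[!miss], vals[!miss], xout = grid$t,
                            rule = 2)$y
    n_filled <- sum(miss)
    vals <- ifelse(miss, filled, vals)
    message(n_filled, " temperature day(s) filled by interpolation")
  }
  structure(
    list(season_label = grid$season_label, values = vals,
         n_filled = n_filled),
    class = "temperature_series")
}

#' Read limnological depth profiles
#'
#' Parses the water-column sampling file: one row per (date, depth)
#' measurement of primary production (PPR, ugC/(L day)) and/or
#' chlorophyll-a (CHL, ug/L). Rows with non-positive depth or a negative
#' measurement are rejected with a message; a blank measurement leaves the
#' other variable's value usable. Duplicate (date, depth) rows are kept --
#' aggregation happens downstream.
#'
#' @param path CSV with columns \code{date}, \code{depth_m}, and at least one
#'   of \code{ppr}, \code{chl}.
#' @return Data frame of class \code{"limno_profiles"} with columns
#'   \code{date} (Date), \code{depth_m}, \code{ppr}, \code{chl}.
#' @export
read_limno_profiles <- function(path) {
  if (!file.exists(path)) stop("limno profile file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "depth_m") %in% names(raw)) ||
      !any(c("ppr", "chl") %in% names(raw)))
    stop("limno file needs columns 'date', 'depth_m' and 'ppr' and/or 'chl': ",
         path)
  ppr <- if ("ppr" %in% names(raw))
    suppressWarnings(as.numeric(raw$ppr)) else rep(NA_real_, nrow(raw))
  chl <- if ("chl" %in% names(raw))
    suppressWarnings(as.numeric(raw$chl)) else rep(NA_real_, nrow(raw))
  depth <- suppressWarnings(as.numeric(raw$depth_m))
  bad <- is.na(depth) | depth <= 0 |
    (!is.na(ppr) & ppr < 0) | (!is.na(chl) & chl < 0)
  if (any(bad))
    message(sum(bad), " limno row(s) rejected (bad depth or negative value)")
  out <- data.frame(date = as.Date(raw$date[!bad]),
                    depth_m = depth[!bad],
                    ppr = ppr[!bad], chl = chl[!bad])
  rownames(out) <- NULL
  class(out) <- c("limno_profiles", "data.frame")
  out
}
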