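#' Seasonal biological response above the chemocline
#'
#' Collapses a season's depth profiles into the scalar the regression uses:
#' the unweighted mean of every qualifying measurement of the chosen
#' variable, where "qualifying" means sampled October 1 -- December 31 of
#' \code{season_label} and no deeper than \code{depth_cutoff} (the
#' chemocline; stream water enters directly beneath the ice, so only the
#' oxic upper column responds to discharge).
#'
#' @param profiles A [read_limno_profiles()] data frame.
#' @param variable \code{"ppr"} (ugC/(L day)) or \code{"chl"} (ug/L).
#' @param season_label Calendar year of the Oct--Dec window.
#' @param depth_cutoff Maximum depth in metres (default 11).
#' @return Object of class \code{"seasonal_response"}: \code{variable},
#'   \code{season_label}, \code{y}, \code{n_obs}.
#' @export
seasonal_response <- function(profiles, variable = c("ppr", "chl"),
                              season_label, depth_cutoff = 11) {
  variable <- match.arg(variable)
  lo <- as.Date(sprintf("%d-10-01", season_label))
  hi <- as.Date(sprintf("%d-12-31", season_label))
  v <- profiles[[variable]]
  ok <- !is.na(v) & profiles$date >= lo & profiles$date <= hi &
    profiles$depth_m <= depth_cutoff
  if (!any(ok))
    stop("missing season: no qualifying ", variable,
         " measurements in Oct-Dec ", season_label)
  structure(
    list(variable = variable, season_label = as.integer(season_label),
         y = mean(v[ok]), n_obs = sum(ok)),
    class = "seasonal_response")
}

#' Pair seasonal responses with the previous season's discharge curves
#'
#' The biology of the early austral summer is driven by nutrient input from
#' the previous flow season, so response year s is paired with the discharge
#' curves labelled s - 1 (December s-1 through January s). Rows are kept
#' only when the response and the lagged latent curve for every requested
#' stream exist.
#'
#' @param responses List of [seasonal_response()] objects (one per season).
#' @param latents Named list from [impute_all()]
#'   (\code{"<stream>|<season>"}).
#' @param streams Ordered character vector of stream ids required per row.
#' @param min_rows Minimum usable rows (default 3).
#' @return Object of class \code{"lagged_design"}: list of rows, each with
#'   \code{response} and \code{covariates} (stream-named latent curves);
#'   attributes \code{streams} and \code{variable}.
#' @export
build_lagged_design <- function(responses, latents, streams, min_rows = 3) {
  rows <- list()
  for (resp in responses) {
    keys <- paste(streams, resp$season_label - 1L, sep = "|")
    if (all(keys %in% names(latents))) {
      cov <- stats::setNames(latents[keys], streams)
      for (s in streams)
        stopifnot(resp$season_label - cov[[s]]$season_label == 1L)
      rows[[length(rows) + 1L]] <- list(response = resp, covariates = cov)
    }
  }
  if (length(rows) < min_rows)
    stop("insufficient data: only ", length(rows),
         " complete response/lagged-discharge rows (need ", min_rows, ")")
  structure(rows,
            streams = streams,
            variable = rows[[1]]$response$variable,
            class = "lagged_design")
}

#' @export
print.lagged_design <- function(x, ...) {
  cat(sprintf(
    "Lagged design: %d seasons of %s vs previous-season discharge (%s)\n",
    length(x), toupper(attr(x, "variable")),
    paste(attr(x, "streams"), collapse = ", ")))
  invisible(x)
}
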