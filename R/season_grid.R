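#' Equidistant December--January season grid
#'
#' Constructs the common time grid on which every functional object in the
#' pipeline lives: daily nodes spanning the austral-summer flow season,
#' December 1 of \code{season_label} through January 31 of
#' \code{season_label + 1}. All quadrature in the scalar-on-function stage
#' assumes this grid is equidistant, so \code{dt} is a single spacing shared
#' by every interval.
#'
#' @param season_label Integer calendar year of the season's December.
#' @param dt Grid spacing in days. Must divide the 61-day horizon exactly.
#' @param start_month_day,end_month_day Character \code{"MM-DD"} bounds of the
#'   flow season; the end day belongs to the following calendar year when its
#'   month precedes the start month.
#'
#' @return An object of class \code{"season_grid"} with components
#'   \code{season_label}, \code{dates} (Date vector of nodes), \code{t}
#'   (times in days from the first node), \code{dt}, \code{M} (number of
#'   intervals), and \code{T} (horizon length \code{M * dt}).
#' @examples
#' g <- season_grid(1996)
#' g$M      # 61 daily intervals
#' range(g$dates)
#' @export
season_grid <- function(season_label, dt = 1,
                        start_month_day = "12-01",
                        end_month_day = "01-31") {
  stopifnot(length(season_label) == 1, is.finite(season_label))
  season_label <- as.integer(season_label)
  start <- as.Date(sprintf("%d-%s", season_label, start_month_day))
  end_year <- season_label +
    as.integer(sub("-.*", "", end_month_day) < sub("-.*", "", start_month_day))
  end <- as.Date(sprintf("%d-%s", end_year, end_month_day))
  if (end <= start) stop("season grid end must fall after its start")
  horizon <- as.numeric(end - start)
  if (dt <= 0 || abs(horizon / dt - round(horizon / dt)) > 1e-9)
    stop("dt must be a positive divisor of the ", horizon, "-day horizon")
  M <- as.integer(round(horizon / dt))
  t <- seq(0, horizon, by = dt)
  structure(
    list(season_label = season_label,
         dates = start + t,
         t = t, dt = dt, M = M, T = M * dt),
    class = "season_grid")
}

#' @export
print.season_grid <- function(x, ...) {
  cat(sprintf("Season grid %d: %s .. %s  (%d nodes, dt = %g d, T = %g d)\n",
              x$season_label, format(x$dates[1]),
              format(x$dates[length(x$dates)]), x$M + 1L, x$dt, x$T))
  invisible(x)
}

# map calendar dates onto grid node indices; NA for dates off the grid
grid_node_index <- function(grid, dates) {
  match(as.Date(dates), grid$dates)
}
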