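# Independent oracles and small fixture builders shared across tests.

# hand-built equidistant grid (bypasses the calendar constructor so tiny
# toy problems are possible)
toy_grid <- function(M, dt = 1, season_label = 2000L) {
  structure(
    list(season_label = season_label,
         dates = as.Date("2000-12-01") + seq(0, M * dt, by = dt),
         t = seq(0, M * dt, by = dt), dt = dt, M = as.integer(M),
         T = M * dt),
    class = "season_grid")
}

toy_obs <- function(grid, obs_idx, values, zeta = 0.01, stream = "s") {
  structure(
    list(stream_id = stream, season_label = grid$season_label,
         obs_idx = obs_idx, obs_times = grid$t[obs_idx], values = values,
         L = length(obs_idx), zeta = zeta),
    class = "log_discharge_obs")
}

toy_temp <- function(grid, values) {
  structure(list(season_label = grid$season_label, values = values,
                 n_filled = 0L),
            class = "temperature_series")
}

# covariance-form Gaussian conditioning: an independent route to the
# posterior of x | y when the prior precision Q is invertible.
# x ~ N(mu, Q^-1), y = A x + e, e ~ N(0, sigma_e2 I)
dense_conditioning_oracle <- function(mu, Q, obs_idx, y, sigma_e2) {
  S <- solve(as.matrix(Q))
  A <- diag(length(mu))[obs_idx, , drop = FALSE]
  V <- A %*% S %*% t(A) + diag(sigma_e2, length(obs_idx))
  K <- S %*% t(A) %*% solve(V)
  post_mean <- as.numeric(mu + K %*% (y - A %*% mu))
  post_cov <- S - K %*% A %*% S
  list(mean = post_mean, sd = sqrt(pmax(diag(post_cov), 0)))
}

# precision-form dense computation (works for the singular RW prior too,
# as long as at least one node is observed)
dense_precision_oracle <- function(mu, Q, obs_idx, y, sigma_e2) {
  n <- length(mu)
  Qd <- as.matrix(Q)
  AtA <- matrix(0, n, n)
  AtA[cbind(obs_idx, obs_idx)] <- 1
  Aty <- numeric(n); Aty[obs_idx] <- y
  Qp <- Qd + AtA / sigma_e2
  post_mean <- solve(Qp, Qd %*% mu + Aty / sigma_e2)
  list(mean = as.numeric(post_mean),
       sd = sqrt(pmax(diag(solve(Qp)), 0)))
}

# brute-force term-by-term left-Riemann quadrature
brute_quadrature <- function(x, phi, dt) {
  M <- length(x) - 1
  s <- 0
  for (m in seq_len(M)) s <- s + phi[m] * x[m] * dt
  s
}

# uncentred quadrature correlation of two curves on an equidistant grid
quad_corr <- function(a, b, dt = 1) {
  M <- length(a) - 1
  ip <- function(f, g) sum(f[seq_len(M)] * g[seq_len(M)]) * dt
  ip(a, b) / sqrt(ip(a, a) * ip(b, b))
}

# build a lagged-design object directly from curve matrices (one latent
# per stream, shared across toy tests)
toy_design <- function(y_values, curves_by_stream, grid, seasons = NULL,
                       zeta = 0.01) {
  streams <- names(curves_by_stream)
  n <- length(y_values)
  rows <- lapply(seq_len(n), function(i) {
    cov <- lapply(streams, function(st) {
      structure(list(stream_id = st,
                     season_label = if (is.null(seasons)) 1999L + i - 1L
                                    else seasons[i] - 1L,
                     mean = curves_by_stream[[st]][i, ], sd = NULL,
                     draws = NULL, hyper_summary = NULL, improper = FALSE,
                     zeta = zeta, L = ncol(curves_by_stream[[st]])),
                class = "latent_discharge")
    })
    names(cov) <- streams
    list(response = structure(
           list(variable = "ppr",
                season_label = if (is.null(seasons)) 2000L + i - 1L
                               else seasons[i],
                y = y_values[i], n_obs = 1L),
           class = "seasonal_response"),
         covariates = cov)
  })
  structure(rows, streams = streams, variable = "ppr",
            class = "lagged_design")
}

write_csv_text <- function(text, file = tempfile(fileext = ".csv")) {
  writeLines(text, file)
  file
}
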