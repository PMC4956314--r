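#' Scalar-on-function linear regression via quadrature scores
#'
#' Fits the reduced form of the functional linear model
#' \deqn{Y_i = \alpha + \sum_j \int_0^T \beta_j(t) X_{ij}(t)\,dt + \epsilon_i}
#' after basis expansion \eqn{\beta_j(t) = \sum_k \gamma_{jk}\phi_k(t)}: an
#' ordinary (optionally ridge-penalized) linear model of the response on the
#' quadrature scores, minimizing
#' \code{||y - alpha - Z gamma||^2 + lambda ||gamma||^2} with the intercept
#' unpenalized. With \code{lambda = 0} and a full-rank design this is exact
#' least squares.
#'
#' @param y Numeric response vector (one scalar per season), length >= 3.
#' @param Z Score matrix from [compute_scores()] (or any numeric matrix with
#'   one row per element of \code{y}).
#' @param lambda Non-negative ridge penalty on the score coefficients.
#' @param basis Optional [make_basis()] object; stored so coefficient curves
#'   can be reconstructed and plotted.
#' @param streams Optional stream ids giving the stream-major column
#'   grouping of \code{Z} (defaults to one group spanning all columns).
#' @param seasons Optional season labels for the rows.
#' @return An object of class \code{"sofr"}: coefficients \code{alpha} and
#'   \code{gamma}, \code{fitted}, \code{residuals}, \code{r2},
#'   \code{se_fit} (standard error of each fitted value), \code{sigma2},
#'   \code{df} (effective degrees of freedom, trace of the smoother),
#'   \code{loocv} (closed-form leave-one-out score), \code{lambda}, and the
#'   ingredients needed by the methods.
#' @seealso [select_lambda()], [reconstruct_beta()],
#'   [fit_per_stream_models()], [ensemble_predict()]
#' @export
sofr <- function(y, Z, lambda = 0, basis = NULL, streams = NULL,
                 seasons = NULL) {
  Z <- as.matrix(Z)
  n <- length(y)
  if (n < 3) stop("insufficient data: need at least 3 observations")
  if (nrow(Z) != n) stop("nrow(Z) must equal length(y)")
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0)
    stop("lambda must be a single non-negative number")
  p <- ncol(Z)
  if (p < 1) stop("Z must have at least one column")
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps)
    stop("degenerate response: y has zero variance, R^2 undefined")

  zbar <- colMeans(Z)
  Zc <- sweep(Z, 2, zbar)
  yc <- y - mean(y)
  ch <- tryCatch(chol(crossprod(Zc) + diag(lambda, p)),
                 error = function(e) NULL)
  if (is.null(ch))
    stop("singular score cross-product at lambda = ", lambda,
         "; increase lambda or reduce K")
  Minv <- chol2inv(ch)                       # (Zc'Zc + lambda I)^{-1}
  gamma <- as.numeric(Minv %*% crossprod(Zc, yc))
  names(gamma) <- colnames(Z)
  alpha <- mean(y) - sum(zbar * gamma)
  fitted <- as.numeric(alpha + Z %*% gamma)
  resid <- y - fitted
  sse <- sum(resid^2)

  S <- Zc %*% Minv %*% t(Zc)                 # smoother without the mean part
  H <- matrix(1 / n, n, n) + S
  hat <- diag(H)
  df <- sum(hat)
  sigma2 <- if (n - df > 1e-8) sse / (n - df) else NA_real_
  se_fit <- if (is.na(sigma2)) rep(NA_real_, n) else
    sqrt(sigma2 * rowSums(H * H))
  loocv <- if (any(hat > 1 - 1e-10)) Inf else
    mean((resid / (1 - hat))^2)

  structure(
    list(alpha = alpha, gamma = gamma, lambda = lambda,
         fitted = fitted, residuals = resid,
         r2 = 1 - sse / sst, se_fit = se_fit,
         sigma2 = sigma2, df = df, hat = hat, loocv = loocv,
         y = y, Z = Z, zbar = zbar, Minv = Minv, n = n,
         basis = basis,
         streams = if (is.null(streams)) "X" else streams,
         K = if (is.null(basis)) p else basis$K,
         seasons = seasons,
         gamma_cov = if (is.na(sigma2)) NULL else
           sigma2 * Minv %*% crossprod(Zc) %*% Minv),
    class = "sofr")
}

#' @export
print.sofr <- function(x, ...) {
  cat(sprintf(
    "Scalar-on-function fit: n = %d, %d score column(s), lambda = %g\n",
    x$n, length(x$gamma), x$lambda))
  cat(sprintf("  R-squared = %.2f%%,  effective df = %.2f\n",
              100 * x$r2, x$df))
  invisible(x)
}

#' @export
summary.sofr <- function(object, ...) {
  se <- if (is.null(object$gamma_cov)) rep(NA_real_, length(object$gamma))
        else sqrt(pmax(diag(object$gamma_cov), 0))
  tab <- data.frame(estimate = object$gamma, std_error = se)
  out <- list(coefficients = tab, alpha = object$alpha, r2 = object$r2,
              lambda = object$lambda, sigma = sqrt(object$sigma2),
              df = object$df, n = object$n, loocv = object$loocv)
  class(out) <- "summary.sofr"
  out
}

#' @export
print.summary.sofr <- function(x, ...) {
  cat(sprintf("Scalar-on-function regression (ridge lambda = %g)\n\n",
              x$lambda))
  cat(sprintf("Intercept alpha: %.4g\n", x$alpha))
  cat("Score coefficients gamma:\n")
  print(x$coefficients, digits = 4)
  cat(sprintf("\nR-squared: %.2f%%   residual sd: %.4g   LOOCV: %.4g\n",
              100 * x$r2, x$sigma, x$loocv))
  invisible(x)
}

#' @export
coef.sofr <- function(object, ...) c(alpha = object$alpha, object$gamma)

#' @export
fitted.sofr <- function(object, ...) object$fitted

#' @export
residuals.sofr <- function(object, ...) object$residuals

#' Predict from a scalar-on-function fit
#'
#' @param object A [sofr()] fit.
#' @param newdata New score matrix with the same columns as the training
#'   scores; omitted means in-sample predictions.
#' @param se.fit Also return standard errors of the predicted mean.
#' @param ... Unused.
#' @return Numeric predictions, or a list \code{(fit, se.fit)}.
#' @export
predict.sofr <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) {
    if (!se.fit) return(object$fitted)
    return(list(fit = object$fitted, se.fit = object$se_fit))
  }
  newdata <- as.matrix(newdata)
  pred <- as.numeric(object$alpha + newdata %*% object$gamma)
  if (!se.fit) return(pred)
  Zc0 <- sweep(newdata, 2, object$zbar)
  A <- object$Minv %*% crossprod(sweep(object$Z, 2, object$zbar)) %*%
    object$Minv
  v <- object$sigma2 * (1 / object$n + rowSums((Zc0 %*% A) * Zc0))
  list(fit = pred, se.fit = sqrt(pmax(v, 0)))
}

#' @export
simulate.sofr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(object$sigma2)
  as.data.frame(replicate(nsim, object$fitted +
                            stats::rnorm(object$n, 0, s)))
}

#' Reconstruct the functional coefficient curves
#'
#' Maps the fitted score coefficients back to curves:
#' \code{beta_j(t_m) = sum_k gamma_jk phi_k(t_m)}, one column per stream.
#'
#' @param fit A [sofr()] fit.
#' @param basis A [make_basis()] with the K the fit used (defaults to the
#'   basis stored in the fit).
#' @return \code{(M+1) x J} matrix of coefficient curves.
#' @export
reconstruct_beta <- function(fit, basis = fit$basis) {
  if (is.null(basis)) stop("no basis available to reconstruct beta")
  J <- length(fit$gamma) / basis$K
  if (J != round(J))
    stop("K mismatch: ", length(fit$gamma),
         " coefficients do not split into groups of K = ", basis$K)
  G <- matrix(fit$gamma, nrow = basis$K)
  B <- basis$values %*% G
  colnames(B) <- if (length(fit$streams) == J) fit$streams else
    paste0("stream", seq_len(J))
  B
}

#' @export
plot.sofr <- function(x, ...) {
  B <- reconstruct_beta(x)
  t <- x$basis$grid$t
  graphics::matplot(t, B, type = "l", lty = 1, lwd = 2,
                    xlab = "day of flow season", ylab = "beta(t)", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", colnames(B), col = seq_len(ncol(B)),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Choose the ridge penalty by closed-form leave-one-out cross-validation
#'
#' For a linear smoother the LOO residual is \code{(y_i - yhat_i)/(1 -
#' H_ii)}, so the full cross-validation score costs one fit per candidate.
#' Ties (within numerical tolerance) are broken toward the larger, more
#' stable penalty -- relevant at the small n of this application.
#'
#' @param y,Z As in [sofr()].
#' @param lambdas Candidate penalties (non-empty).
#' @return The chosen lambda, with the score table in attribute
#'   \code{"scores"}.
#' @export
select_lambda <- function(y, Z, lambdas = default_lambda_grid()) {
  if (length(lambdas) == 0) stop("candidate lambda grid is empty")
  scores <- vapply(lambdas, function(l) {
    f <- tryCatch(sofr(y, Z, lambda = l), error = function(e) NULL)
    if (is.null(f)) Inf else f$loocv
  }, numeric(1))
  best <- min(scores)
  tol <- 1e-10 * (1 + abs(best))
  chosen <- max(lambdas[scores <= best + tol])
  structure(chosen, scores = data.frame(lambda = lambdas, loocv = scores))
}

#' @rdname select_lambda
#' @export
default_lambda_grid <- function() c(0, 10^seq(-3, 6, by = 1))

#' Fit one single-stream model per stream
#'
#' The field data are short (just over a decade of seasons), so rather than
#' one joint multi-stream fit, one J = 1 model is fitted per stream and the
#' predictions averaged afterwards ([ensemble_predict()]).
#'
#' @param design A [build_lagged_design()] object.
#' @param basis A [make_basis()].
#' @param lambda A fixed penalty, or \code{NULL} to select per stream by
#'   [select_lambda()].
#' @param covariate_scale Passed to [compute_scores()].
#' @param lambdas Candidate grid when \code{lambda} is \code{NULL}.
#' @return Named list of [sofr()] fits, one per stream, class
#'   \code{"sofr_list"}.
#' @export
fit_per_stream_models <- function(design, basis, lambda = NULL,
                                  covariate_scale = "log",
                                  lambdas = default_lambda_grid()) {
  streams <- attr(design, "streams")
  sc <- compute_scores(design, basis, covariate_scale)
  fits <- list()
  for (j in seq_along(streams)) {
    cols <- (j - 1L) * basis$K + seq_len(basis$K)
    Zj <- sc$Z[, cols, drop = FALSE]
    lj <- if (is.null(lambda)) as.numeric(select_lambda(sc$y, Zj, lambdas))
          else lambda
    fits[[streams[j]]] <- sofr(sc$y, Zj, lambda = lj, basis = basis,
                               streams = streams[j], seasons = sc$seasons)
  }
  class(fits) <- "sofr_list"
  fits
}

#' Ensemble prediction across the per-stream models
#'
#' Per-season prediction = arithmetic mean of the per-stream model
#' predictions; its band is \code{mean +/- 2 SE} where the ensemble SE
#' combines the per-model prediction variances as
#' \code{sqrt(mean(se_j^2))}; the headline fit statistic is the arithmetic
#' mean of the per-model coefficients of determination.
#'
#' @param fits A \code{sofr_list} from [fit_per_stream_models()]; all fits
#'   must share the same response vector.
#' @return Object of class \code{"sofr_ensemble"}: data frame
#'   \code{predictions} (season, y, pred, se, lower, upper), \code{r2}
#'   (named per-model values), \code{r2_avg}.
#' @export
ensemble_predict <- function(fits) {
  ys <- lapply(fits, `[[`, "y")
  if (!all(vapply(ys, function(v) isTRUE(all.equal(v, ys[[1]])),
                  logical(1))))
    stop("alignment error: per-stream fits do not share the response vector")
  P <- vapply(fits, fitted, numeric(length(ys[[1]])))
  V <- vapply(fits, function(f) f$se_fit^2, numeric(length(ys[[1]])))
  pred <- rowMeans(P)
  se <- sqrt(rowMeans(V))
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  structure(
    list(predictions = data.frame(
           season = if (is.null(fits[[1]]$seasons))
             seq_along(pred) else fits[[1]]$seasons,
           y = ys[[1]], pred = pred, se = se,
           lower = pred - 2 * se, upper = pred + 2 * se),
         r2 = r2, r2_avg = mean(r2)),
    class = "sofr_ensemble")
}

#' @export
print.sofr_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d single-stream models\n", length(x$r2)))
  cat("  per-model R-squared: ",
      paste(sprintf("%s %.2f%%", names(x$r2), 100 * x$r2),
            collapse = ", "), "\n")
  cat(sprintf("  averaged R-squared: %.2f%%\n", 100 * x$r2_avg))
  invisible(x)
}

#' @export
plot.sofr_ensemble <- function(x, ...) {
  p <- x$predictions
  ylim <- range(p$y, p$lower, p$upper, na.rm = TRUE)
  graphics::plot(p$season, p$y, pch = 16, ylim = ylim,
                 xlab = "season", ylab = "response", ...)
  graphics::points(p$season, p$pred, pch = 8, col = "red")
  graphics::segments(p$season, p$lower, p$season, p$upper,
                     lty = 2, col = "red")
  invisible(x)
}
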