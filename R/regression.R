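#' Ordinary least squares fit with full classical reporting
#'
#' Thin, fully reported wrapper around [stats::lm()]: per-coefficient
#' estimates with homoskedastic standard errors, two-sided t tests, R^2,
#' adjusted R^2 (which may legitimately be negative and is not clipped),
#' and the model F test.
#'
#' @param x Predictors: data.frame, matrix or numeric vector (one column
#'   per predictor, no missing cells).
#' @param y Numeric response, same length as `nrow(x)`.
#' @return Object of class `"lakesize_ols"`: `coefficients` (data.frame
#'   with term, estimate, se, t, p; first row the intercept), `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `model_p`, `n`, `k`, `sigma`,
#'   `residuals`, `fitted`.
#' @export
#' @examples
#' fit <- ols_fit(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' coef(fit)          # intercept 1, slope 0.6
#' fit$r_squared      # 0.36
ols_fit <- function(x, y) {
  if (is.null(dim(x))) x <- data.frame(x = x)
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("x and y dimensions disagree")
  if (anyNA(x) || anyNA(y)) stop("missing cells in design or response")
  k <- ncol(x)
  if (length(y) <= k + 1)
    stop("need n > k + 1 observations (n = ", length(y), ", k = ", k, ")")
  dat <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  # constant response: define R^2 = 0 (nothing to explain), F undefined
  if (!is.finite(sm$r.squared)) {
    sm$r.squared <- 0
    sm$adj.r.squared <- 0
  }
  ct <- sm$coefficients
  coefs <- data.frame(term = c("(Intercept)", names(x)),
                      estimate = ct[, 1], se = ct[, 2],
                      t = ct[, 3], p = ct[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(list(coefficients = coefs,
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
                 model_p = model_p,
                 n = length(y), k = k, sigma = sm$sigma,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit)),
            class = "lakesize_ols")
}

#' @export
print.lakesize_ols <- function(x, digits = 3, ...) {
  cat(sprintf("OLS fit: n = %d, k = %d, R2 = %.*f, adj R2 = %.*f, F = %.*f, P = %.3g\n",
              x$n, x$k, digits, x$r_squared, digits, x$adj_r_squared,
              digits, x$f_statistic, x$model_p))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.lakesize_ols <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.lakesize_ols <- function(object, ...) object$residuals

#' Variance inflation factors
#'
#' Multicollinearity screen for a predictor set: for each predictor j,
#' \eqn{VIF_j = 1 / (1 - R^2_j)} where \eqn{R^2_j} comes from regressing
#' predictor j on all the others. Values below 3 are taken as absence of
#' problematic multicollinearity. Exactly collinear predictors yield
#' `Inf` with a warning rather than an error.
#'
#' @param x Data.frame or matrix with >= 2 predictor columns, n > k.
#' @return Named numeric vector of VIFs (>= 1).
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("VIF needs at least 2 predictors")
  if (anyNA(x)) stop("missing cells in design")
  if (nrow(x) <= ncol(x)) stop("need n > k observations")
  out <- vapply(seq_along(x), function(j) {
    # exact collinearity is detected below; silence summary.lm's perfect-fit note
    r2 <- suppressWarnings(
      summary(stats::lm(x[[j]] ~ ., data = x[-j]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(x)
  if (any(!is.finite(out)))
    warning("exactly collinear predictor(s): ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Hierarchical partitioning of explained variance
#'
#' Decomposes a multiple regression's goodness of fit (R^2) into each
#' predictor's independent contribution I and joint contribution J. All
#' 2^k predictor subsets are fitted; I_j is the average R^2 increase when
#' predictor j enters, taken over all k! orderings of entry (computed via
#' subset-size weights, not by enumerating orderings). J_j is the marginal
#' R^2 of j alone minus I_j. By construction the sum of all I and J equals
#' the full-model R^2.
#'
#' Independent contributions are also expressed as percentages of their
#' sum — the "I (%)" reported alongside the multiple regressions. Negative
#' I values (possible when suppression is present) are reported as-is with
#' a warning, never floored.
#'
#' @param x Predictors (1 <= k <= 12 columns; 2^k fits).
#' @param y Numeric response.
#' @return Object of class `"hier_part"`: `partition` (data.frame with
#'   predictor, independent, joint, total, i_pct), `r_squared_full`, `n`,
#'   `k`.
#' @export
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(30), b = rnorm(30))
#' hier_part(x, x$a + 0.5 * x$b + rnorm(30, sd = 0.3))
hier_part <- function(x, y) {
  if (is.null(dim(x))) x <- data.frame(x = x)
  x <- as.data.frame(x)
  k <- ncol(x)
  if (k < 1 || k > 12) stop("hier_part supports 1 to 12 predictors")
  if (anyNA(x) || anyNA(y)) stop("missing cells in design or response")
  n <- length(y)
  if (n <= k + 1) stop("need n > k + 1 observations")

  xm <- as.matrix(x)
  if (qr(cbind(1, xm))$rank < k + 1)
    stop("rank-deficient design; hierarchical partitioning undefined")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant response")

  # R^2 for every predictor subset, indexed by bitmask
  nsub <- 2L^k
  r2 <- numeric(nsub)
  for (m in seq_len(nsub - 1L)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L)
    f <- stats::lm.fit(cbind(1, xm[, idx, drop = FALSE]), y)
    r2[m + 1L] <- 1 - sum(f$residuals^2) / tss
  }

  wts <- exp(lgamma(0:(k - 1) + 1) + lgamma(k - (0:(k - 1))) - lgamma(k + 1))
  indep <- numeric(k)
  for (j in seq_len(k)) {
    bit <- bitwShiftL(1L, j - 1L)
    others <- seq_len(nsub) - 1L
    others <- others[bitwAnd(others, bit) == 0L]
    sizes <- vapply(others, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) != 0L), numeric(1))
    gains <- r2[bitwOr(others, bit) + 1L] - r2[others + 1L]
    indep[j] <- sum(wts[sizes + 1] * gains)
  }
  marg <- r2[bitwShiftL(1L, seq_len(k) - 1L) + 1L]
  joint <- marg - indep
  if (any(indep < 0))
    warning("negative independent contribution(s) for: ",
            paste(names(x)[indep < 0], collapse = ", "),
            " (reported as-is)")
  part <- data.frame(predictor = names(x), independent = indep,
                     joint = joint, total = marg,
                     i_pct = 100 * indep / sum(indep),
                     stringsAsFactors = FALSE)
  structure(list(partition = part, r_squared_full = r2[nsub],
                 n = n, k = k),
            class = "hier_part")
}

#' @export
print.hier_part <- function(x, digits = 3, ...) {
  cat(sprintf("Hierarchical partitioning (k = %d, n = %d, full-model R2 = %.*f)\n",
              x$k, x$n, digits, x$r_squared_full))
  print(format(x$partition, digits = digits), row.names = FALSE)
  invisible(x)
}
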