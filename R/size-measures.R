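#' Shell size estimator S
#'
#' Reduces a shell's height and width (mm) to one number: the side length
#' of the square with the same area as the height-by-width rectangle,
#' \eqn{S = \sqrt{h w}}. S carries information from both dimensions, making
#' planispiral (wide, low) and turriform (tall, narrow) shells comparable.
#'
#' S is symmetric in its arguments and scale-equivariant:
#' `shell_size(k*h, k*w) == k * shell_size(h, w)`.
#'
#' @param height,width Shell height and width in mm; strictly positive,
#'   vectorised.
#' @return S in mm.
#' @export
#' @examples
#' shell_size(4, 1)   # 2
#' shell_size(2, 8)   # 4
shell_size <- function(height, width) {
  if (length(height) != length(width))
    stop("height and width must have equal length")
  if (anyNA(height) || anyNA(width))
    stop("height/width must not contain missing values")
  if (any(height <= 0) || any(width <= 0))
    stop("height and width must be strictly positive")
  sqrt(height * width)
}

#' Four log10 size measures for one fauna
#'
#' Summarises the raw S values (mm) of a lake's measured species by mean,
#' maximum, minimum and raw range, each log10-transformed:
#' `S_max = log10(max)`, `S_min = log10(min)`,
#' `S_mean = log10(mean)` (arithmetic mean of raw S by default), and
#' `S_range = log10(max - min)` — the log of the raw size span, not the
#' difference of logs (switchable via `range_method`). `S_range` is `NA`
#' when fewer than two species are present or all sizes coincide.
#'
#' @param s Vector of raw S values in mm (>= 1 positive value).
#' @param lake_id Optional identifier carried into the result.
#' @param mean_method,range_method See [lakesize_config()].
#' @return One-row data.frame: `lake_id`, `n_measured`, `S_mean`, `S_max`,
#'   `S_min`, `S_range` (log10 mm).
#' @export
#' @examples
#' fauna_size_summary(c(1, 10, 100))
fauna_size_summary <- function(s, lake_id = NA_character_,
                               mean_method = c("arithmetic", "geometric"),
                               range_method = c("raw_diff", "log_diff")) {
  mean_method <- match.arg(mean_method)
  range_method <- match.arg(range_method)
  if (length(s) == 0) stop("empty size vector")
  if (anyNA(s) || any(s <= 0)) stop("sizes must be positive and non-missing")
  s_max <- max(s); s_min <- min(s)
  s_mean <- if (mean_method == "arithmetic") log10(mean(s)) else mean(log10(s))
  s_range <- if (length(s) < 2 || s_max == s_min) NA_real_
             else if (range_method == "raw_diff") log10(s_max - s_min)
             else log10(s_max) - log10(s_min)
  data.frame(lake_id = lake_id, n_measured = length(s),
             S_mean = s_mean, S_max = log10(s_max), S_min = log10(s_min),
             S_range = s_range, stringsAsFactors = FALSE)
}

#' Per-lake size measures for a filtered species table
#'
#' @param species Filtered species table (measured species only, or with a
#'   `size_missing` flag, which is honoured).
#' @param config A [lakesize_config()]; supplies mean/range conventions.
#' @return A data.frame with one row per lake, as [fauna_size_summary()].
#' @export
fauna_size_table <- function(species, config = lakesize_config()) {
  if ("size_missing" %in% names(species))
    species <- species[!species$size_missing, , drop = FALSE]
  if (nrow(species) == 0) stop("no measured species")
  s <- shell_size(species$height, species$width)
  parts <- lapply(split(s, species$lake_id), function(v)
    fauna_size_summary(v, mean_method = config$mean_method,
                       range_method = config$range_method))
  out <- do.call(rbind, parts)
  out$lake_id <- names(parts)
  rownames(out) <- NULL
  out
}

#' Adjusted Fisher-Pearson sample skewness G1
#'
#' \deqn{G_1 = \frac{n^2}{(n-1)(n-2)} \frac{m_3}{s^3}}
#' with \eqn{m_3} the mean third central moment and \eqn{s} the (n-1)
#' sample standard deviation. Positive values indicate a right tail.
#'
#' @param x Numeric vector, n >= 3, non-constant.
#' @return G1 (dimensionless).
#' @export
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 values")
  s <- stats::sd(x)
  if (s == 0) stop("skewness undefined for constant data")
  m3 <- mean((x - mean(x))^3)
  n^2 / ((n - 1) * (n - 2)) * m3 / s^3
}

#' Distribution diagnostics for a size sample
#'
#' Skewness G1 plus the Shapiro-Wilk normality test, as used to judge
#' whether the pooled log10 size distribution departs from normality.
#'
#' @param x Numeric vector (typically log10 S); 3 <= n <= 5000 for the
#'   Shapiro-Wilk statistic (the validated range of the algorithm).
#' @return List of class `"size_diagnostics"`: `n`, `skewness_G1`,
#'   `shapiro_W`, `shapiro_P`.
#' @export
size_diagnostics <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("need at least 3 values")
  if (stats::sd(x) == 0) stop("diagnostics undefined for constant data")
  sw <- stats::shapiro.test(x)
  structure(list(n = length(x), skewness_G1 = skewness_g1(x),
                 shapiro_W = unname(sw$statistic),
                 shapiro_P = sw$p.value),
            class = "size_diagnostics")
}

#' @export
print.size_diagnostics <- function(x, ...) {
  cat(sprintf("size distribution (n = %d): G1 = %.3f, Shapiro-Wilk W = %.3f, P = %.3g\n",
              x$n, x$skewness_G1, x$shapiro_W, x$shapiro_P))
  invisible(x)
}
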