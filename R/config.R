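#' Analysis run configuration
#'
#' Collects every tunable of the analysis chain in one validated list.
#' Defaults reproduce the study design: 25% subsample resampling with 1000
#' repetitions, a minimum of four measured species per lake, a two-species
#' floor for subsamples (so ranges remain computable), families considered
#' only when present in more than five lakes, and a 3 Myr dating-uncertainty
#' cutoff for the longevity analysis.
#'
#' @param fraction Fraction of each lake's fauna drawn per resampling
#'   replicate, in (0, 1]. Default 0.25.
#' @param repetitions Number of resampling replicates (>= 1). Default 1000.
#' @param seed Integer seed recorded in run logs; `NULL` leaves the RNG
#'   state untouched.
#' @param min_species Minimum number of measured species for a lake to enter
#'   the analysis. Default 4.
#' @param min_subsample Smallest subsample drawn per lake in the resampling
#'   test. Default 2 (a size range needs two species).
#' @param family_min_lakes A family must be present in at least this many
#'   lakes to enter the family-level battery. Default 6 ("more than five").
#' @param age_uncertainty_max Occurrences dated with uncertainty above this
#'   value (Myr) are excluded from temporal analyses. Default 3.
#' @param exclude_caspian If `TRUE`, the lake named in `caspian_id` is
#'   dropped before fitting (sensitivity analysis for the one very large,
#'   small-bodied fauna). Default `FALSE`.
#' @param caspian_id Lake identifier used by `exclude_caspian`.
#' @param range_method `"raw_diff"` (default) computes the size-range
#'   measure as log10(max S - min S); `"log_diff"` uses
#'   log10(max) - log10(min).
#' @param mean_method `"arithmetic"` (default) takes log10 of the arithmetic
#'   mean of raw S; `"geometric"` averages log10 S directly.
#' @param resample_mode `"literal"` (default) scores the resampling P as the
#'   proportion of resampled slopes strictly greater than the observed
#'   slope; `"two_sided_magnitude"` compares absolute slopes.
#' @param incidence_from `"measured"` (default) builds family incidence from
#'   size-bearing species only; `"all"` uses every record.
#' @param log_predictors Character vector naming the predictors entered on
#'   the log10 scale. Default `c("area", "distance", "richness")`; endemism,
#'   latitude, longitude and beta diversity enter raw.
#'
#' @return A list of class `"lakesize_config"`.
#' @export
#' @examples
#' cfg <- lakesize_config(repetitions = 200, seed = 1)
#' cfg$fraction
lakesize_config <- function(fraction = 0.25,
                            repetitions = 1000,
                            seed = NULL,
                            min_species = 4,
                            min_subsample = 2,
                            family_min_lakes = 6,
                            age_uncertainty_max = 3,
                            exclude_caspian = FALSE,
                            caspian_id = "Caspian Sea",
                            range_method = c("raw_diff", "log_diff"),
                            mean_method = c("arithmetic", "geometric"),
                            resample_mode = c("literal", "two_sided_magnitude"),
                            incidence_from = c("measured", "all"),
                            log_predictors = c("area", "distance", "richness")) {
  range_method <- match.arg(range_method)
  mean_method <- match.arg(mean_method)
  resample_mode <- match.arg(resample_mode)
  incidence_from <- match.arg(incidence_from)
  stopifnot(is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction <= 1)
  stopifnot(is.numeric(repetitions), length(repetitions) == 1,
            repetitions >= 1, repetitions == floor(repetitions))
  stopifnot(min_species >= 1, min_subsample >= 1, family_min_lakes >= 1,
            age_uncertainty_max >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  bad <- setdiff(log_predictors,
                 c("area", "beta", "distance", "endemism",
                   "latitude", "longitude", "richness"))
  if (length(bad))
    stop("unknown predictor(s) in log_predictors: ",
         paste(bad, collapse = ", "))
  structure(list(
    fraction = fraction,
    repetitions = as.integer(repetitions),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    min_species = as.integer(min_species),
    min_subsample = as.integer(min_subsample),
    family_min_lakes = as.integer(family_min_lakes),
    age_uncertainty_max = age_uncertainty_max,
    exclude_caspian = isTRUE(exclude_caspian),
    caspian_id = caspian_id,
    range_method = range_method,
    mean_method = mean_method,
    resample_mode = resample_mode,
    incidence_from = incidence_from,
    log_predictors = log_predictors
  ), class = "lakesize_config")
}

#' Read a run configuration from a YAML file
#'
#' Any field of [lakesize_config()] may appear in the file; unspecified
#' fields keep their defaults. Unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return A `"lakesize_config"` list.
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(lakesize_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(lakesize_config, vals)
}

#' @export
print.lakesize_config <- function(x, ...) {
  cat("lakesize run configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
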