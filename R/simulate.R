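#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical structure the analysis assumes
#' about long-lived lake gastropod faunas: a power-law species-area
#' relationship with lognormal noise, a weakly right-skewed global log10
#' size distribution (skew-normal family), endemism probability increasing
#' logistically with log10 richness, per-family size offsets,
#' height/width aspect ratios drawn so the size estimator round-trips
#' exactly, and stratigraphic occurrence ages within each lake's lifespan.
#'
#' Two generative modes: `"sampling_null"` draws every species' size
#' i.i.d. from the global distribution, so any richness-size-extreme
#' correlation is purely an order-statistics (sampling) effect; in
#' `"structured"` mode the size-distribution scale additionally widens
#' linearly with log10 lake area by `area_scale_coef`, planting a genuine
#' area effect on the size spectrum.
#'
#' @param n_lakes Number of lakes (>= 3). Default 23.
#' @param area_log10_range log10 bounds (km^2) of the uniform area draw.
#' @param sar_c,sar_z Species-area coefficients: richness ~
#'   `round(sar_c * area^sar_z * eps)`, floored at `richness_floor`.
#' @param sar_noise_sd SD of the lognormal SAR noise on the log10 scale.
#' @param richness_floor Smallest generated richness. Default 5 (one above
#'   the inclusion filter's minimum of 4 measured species).
#' @param size_location,size_scale Mean and SD of pooled log10 S (mm).
#' @param size_skew Target skewness G1 of pooled log10 S; 0 gives a
#'   normal distribution. Must lie in (-0.995, 0.995).
#' @param n_families Number of family labels.
#' @param family_offset_sd SD of per-family offsets added to the log10
#'   size location (families differ in typical size).
#' @param aspect_meanlog,aspect_sdlog Lognormal parameters of the
#'   height/width ratio (positive mean: shells typically taller than
#'   wide).
#' @param endemism_intercept,endemism_slope Logistic model of the
#'   single-lake-endemic probability in log10 richness.
#' @param duration_range,origin_max_ma Lake duration bounds (Myr) and the
#'   oldest allowed lake origin (Ma).
#' @param distance_log10_range log10 bounds (km) of the distance draw.
#' @param lat_range,lon_range Centroid coordinate bounds (decimal deg).
#' @param uncertainty_mean_myr Mean of the exponential dating-uncertainty
#'   draw (Myr).
#' @param mode `"sampling_null"` or `"structured"` (see above).
#' @param area_scale_coef Structured-mode widening of the size scale per
#'   unit log10 area (centred); ignored in sampling-null mode.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_lakes = 23,
                       area_log10_range = c(0, 5.6),
                       sar_c = 8, sar_z = 0.25, sar_noise_sd = 0.3,
                       richness_floor = 5,
                       size_location = 0.55, size_scale = 0.45,
                       size_skew = 0.35,
                       n_families = 8, family_offset_sd = 0.12,
                       aspect_meanlog = 0.55, aspect_sdlog = 0.5,
                       endemism_intercept = -2.5, endemism_slope = 1.2,
                       duration_range = c(0.2, 7.1), origin_max_ma = 18,
                       distance_log10_range = c(0.5, 2.3),
                       lat_range = c(37, 49), lon_range = c(-4, 51),
                       uncertainty_mean_myr = 1,
                       mode = c("sampling_null", "structured"),
                       area_scale_coef = 0.15) {
  mode <- match.arg(mode)
  stopifnot(n_lakes >= 3, sar_c > 0, sar_z >= 0, sar_noise_sd >= 0,
            richness_floor >= 1, size_scale > 0, n_families >= 1,
            family_offset_sd >= 0, aspect_sdlog >= 0,
            uncertainty_mean_myr > 0, abs(size_skew) < 0.995,
            diff(area_log10_range) >= 0, diff(duration_range) > 0)
  structure(as.list(environment()), class = "sim_config")
}

# skew-normal shape: delta solving the G1(delta) moment relation
g1_to_delta <- function(g1) {
  if (g1 == 0) return(0)
  g <- abs(g1)
  f <- function(d) {
    m <- d * sqrt(2 / pi)
    (4 - pi) / 2 * m^3 / (1 - m^2)^1.5 - g
  }
  sign(g1) * stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# standardized skew-normal deviates (mean 0, sd 1, skewness G1 -> delta)
rskewnorm_std <- function(n, delta) {
  z <- delta * abs(stats::rnorm(n)) +
       sqrt(1 - delta^2) * stats::rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (z - mu) / sqrt(1 - mu^2)
}

#' Generate a synthetic lake table
#'
#' Areas are drawn log10-uniform; species richness follows the power-law
#' species-area relationship with lognormal noise, floored at
#' `richness_floor`; durations, origins, distances and coordinates are
#' drawn uniformly within their configured ranges. `pct_endemism` is set
#' to the logistic model's expectation and later replaced by the realised
#' share when species are generated.
#'
#' @param config A [sim_config()].
#' @return A lake table (schema of [read_lake_table()], plus `age_top`,
#'   `age_base`).
#' @export
generate_lakes <- function(config) {
  n <- config$n_lakes
  if (n < 3) stop("need at least 3 lakes")
  area <- 10^stats::runif(n, config$area_log10_range[1],
                          config$area_log10_range[2])
  eps <- 10^stats::rnorm(n, 0, config$sar_noise_sd)
  rich <- pmax(config$richness_floor,
               as.integer(round(config$sar_c * area^config$sar_z * eps)))
  duration <- stats::runif(n, config$duration_range[1],
                           config$duration_range[2])
  age_base <- duration + stats::runif(n, 0, pmax(0, config$origin_max_ma - duration))
  p_end <- stats::plogis(config$endemism_intercept +
                         config$endemism_slope * log10(rich))
  data.frame(
    lake_id = sprintf("lake%02d", seq_len(n)),
    latitude = stats::runif(n, config$lat_range[1], config$lat_range[2]),
    longitude = stats::runif(n, config$lon_range[1], config$lon_range[2]),
    area_km2 = area,
    duration_myr = duration,
    pct_endemism = 100 * p_end,
    distance_km = 10^stats::runif(n, config$distance_log10_range[1],
                                  config$distance_log10_range[2]),
    n_species = rich,
    age_top = age_base - duration,
    age_base = age_base,
    avg_beta = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic species table for a lake table
#'
#' Per lake, `n_species` species: log10 S is location + family offset +
#' scale x a standardized skew-normal deviate (scale widened with log10
#' area in structured mode); height and width are back-computed from S
#' and a lognormal aspect ratio so that `sqrt(h * w)` reproduces S
#' exactly; endemic flags are Bernoulli with logistic probability in
#' log10 richness; occurrence ages are uniform within the lake's
#' lifespan (first >= last) with exponential dating uncertainty.
#'
#' @param lakes Lake table from [generate_lakes()].
#' @param config A [sim_config()].
#' @return A species table (schema of [read_species_table()]); the drawn
#'   per-family offsets are attached as attribute `"family_offsets"`.
#' @export
generate_species <- function(lakes, config) {
  fams <- sprintf("Fam%02d", seq_len(config$n_families))
  offsets <- stats::setNames(
    stats::rnorm(config$n_families, 0, config$family_offset_sd), fams)
  delta <- g1_to_delta(config$size_skew)
  la <- log10(lakes$area_km2)
  la_c <- la - mean(la)

  rows <- vector("list", nrow(lakes))
  for (i in seq_len(nrow(lakes))) {
    n <- lakes$n_species[i]
    omega <- config$size_scale
    if (config$mode == "structured")
      omega <- max(0.05, omega * (1 + config$area_scale_coef * la_c[i]))
    fam <- sample(fams, n, replace = TRUE)
    log_s <- config$size_location + offsets[fam] +
             omega * rskewnorm_std(n, delta)
    s <- 10^log_s
    ratio <- stats::rlnorm(n, config$aspect_meanlog, config$aspect_sdlog)
    if (any(ratio <= 0)) stop("non-positive aspect ratio drawn")
    a1 <- stats::runif(n, lakes$age_top[i], lakes$age_base[i])
    a2 <- stats::runif(n, lakes$age_top[i], lakes$age_base[i])
    rows[[i]] <- data.frame(
      species_id = sprintf("%s_sp%04d", lakes$lake_id[i], seq_len(n)),
      lake_id = lakes$lake_id[i],
      family = fam,
      height = s * sqrt(ratio),
      width = s / sqrt(ratio),
      endemic = stats::rbinom(n, 1, stats::plogis(
        config$endemism_intercept + config$endemism_slope * log10(n))) == 1,
      first_age = pmax(a1, a2),
      last_age = pmin(a1, a2),
      age_uncertainty = stats::rexp(n, 1 / config$uncertainty_mean_myr),
      lineage_id = NA_character_,
      clade_rank = NA_integer_,
      horizon = NA_character_,
      horizon_age = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$size_missing <- FALSE
  attr(out, "family_offsets") <- offsets
  out
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Seeds the RNG, draws the lake and species tables, reconciles the lake
#' table's endemism with the realised flags, and attaches the ground-truth
#' parameters needed to score recovery.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the generated tables are an exact function of
#'   (config, seed).
#' @return List of class `"lakesize_sim"`: `lakes`, `species`,
#'   `ground_truth` (list with sar_c, sar_z, size parameters,
#'   endemism model, mode, area_scale_coef, family offsets, seed).
#' @export
#' @examples
#' sim <- simulate_lakesize(sim_config(n_lakes = 6), seed = 1)
#' nrow(sim$lakes)
simulate_lakesize <- function(config = sim_config(), seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  lakes <- generate_lakes(config)
  species <- generate_species(lakes, config)
  realised <- tapply(species$endemic, species$lake_id, mean)
  lakes$pct_endemism <- 100 * as.vector(realised[lakes$lake_id])
  stopifnot(identical(as.vector(table(factor(species$lake_id,
                                             levels = lakes$lake_id))),
                      as.integer(lakes$n_species)))
  gt <- list(sar_c = config$sar_c, sar_z = config$sar_z,
             size_location = config$size_location,
             size_scale = config$size_scale, size_skew = config$size_skew,
             endemism_intercept = config$endemism_intercept,
             endemism_slope = config$endemism_slope,
             mode = config$mode,
             area_scale_coef = if (config$mode == "structured")
               config$area_scale_coef else 0,
             family_offsets = attr(species, "family_offsets"),
             seed = as.integer(seed))
  structure(list(lakes = lakes, species = species, ground_truth = gt),
            class = "lakesize_sim")
}

#' @export
print.lakesize_sim <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d lakes, %d species (mode %s, seed %d)\n",
              nrow(x$lakes), nrow(x$species), x$ground_truth$mode,
              x$ground_truth$seed))
  invisible(x)
}

#' Score parameter recovery on a synthetic dataset
#'
#' Re-estimates from the generated tables: the species-area exponent (OLS
#' of log10 richness on log10 area; pass when the 95% CI covers the true
#' z), the endemism-model slope (logistic regression of the endemic flag
#' on log10 richness; pass on sign agreement), and the area effect on the
#' size spectrum (partial OLS slope of S_range on log10 area controlling
#' for log10 richness — under the sampling null the marginal slope is
#' nonzero through richness alone, so only the partial slope identifies a
#' genuine area effect; pass when the CI covers 0 under the sampling
#' null, or the slope sign matches the planted effect).
#'
#' @param sim A `"lakesize_sim"`.
#' @param config Analysis configuration for the size measures.
#' @return Data.frame: quantity, truth, estimate, ci_lo, ci_hi, pass.
#' @export
score_recovery <- function(sim, config = lakesize_config()) {
  if (is.null(sim$ground_truth)) stop("missing ground truth")
  gt <- sim$ground_truth
  lakes <- sim$lakes; species <- sim$species

  fit_sar <- ols_fit(data.frame(log_area = log10(lakes$area_km2)),
                     log10(lakes$n_species))
  sl <- fit_sar$coefficients[2, ]
  tq <- stats::qt(0.975, fit_sar$n - 2)
  sar <- data.frame(quantity = "sar_z", truth = gt$sar_z,
                    estimate = sl$estimate,
                    ci_lo = sl$estimate - tq * sl$se,
                    ci_hi = sl$estimate + tq * sl$se)
  sar$pass <- sar$truth >= sar$ci_lo & sar$truth <= sar$ci_hi

  rich_sp <- lakes$n_species[match(species$lake_id, lakes$lake_id)]
  if (stats::var(log10(rich_sp)) == 0 ||
      length(unique(species$endemic)) == 1) {
    # constant richness or flags: slope unidentifiable
    end <- data.frame(quantity = "endemism_slope_sign",
                      truth = sign(gt$endemism_slope),
                      estimate = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_)
    end$pass <- NA
  } else {
    gfit <- stats::glm(endemic ~ log10(n), binomial,
                       data = data.frame(endemic = species$endemic,
                                         n = rich_sp))
    b <- summary(gfit)$coefficients[2, ]
    end <- data.frame(quantity = "endemism_slope_sign",
                      truth = sign(gt$endemism_slope),
                      estimate = unname(b[1]),
                      ci_lo = unname(b[1] - 1.96 * b[2]),
                      ci_hi = unname(b[1] + 1.96 * b[2]))
    end$pass <- if (end$truth == 0) end$ci_lo <= 0 & end$ci_hi >= 0
                else sign(end$estimate) == end$truth
  }

  sizes <- fauna_size_table(species, config)
  y <- sizes$S_range
  ok <- !is.na(y)
  li <- match(sizes$lake_id[ok], lakes$lake_id)
  ax <- data.frame(log_area = log10(lakes$area_km2[li]),
                   log_rich = log10(lakes$n_species[li]))
  if (stats::var(ax$log_rich) == 0) ax$log_rich <- NULL
  afit <- ols_fit(ax, y[ok])
  al <- afit$coefficients[afit$coefficients$term == "log_area", ]
  tq <- stats::qt(0.975, afit$n - 2)
  ar <- data.frame(quantity = "area_scale_effect", truth = gt$area_scale_coef,
                   estimate = al$estimate,
                   ci_lo = al$estimate - tq * al$se,
                   ci_hi = al$estimate + tq * al$se)
  ar$pass <- if (gt$area_scale_coef == 0) ar$ci_lo <= 0 & ar$ci_hi >= 0
             else sign(ar$estimate) == sign(gt$area_scale_coef)

  out <- rbind(sar, end, ar)
  rownames(out) <- NULL
  out
}
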