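#' Family-level regression battery
#'
#' Repeats the size-measure regressions within gastropod families to ask
#' whether the fauna-level pattern is general or driven by particular
#' clades. Filters: a family must be present in more than five lakes
#' (strictly, >= `config$family_min_lakes`); (family, lake) cells with a
#' single species are dropped (no size range exists there); families
#' retaining fewer than 3 lakes after cell filtering are skipped with a
#' note. For each qualifying family the four size measures are regressed
#' on log10 within-family richness and log10 lake area — the predictors
#' significant at the fauna level.
#'
#' The two filters commute: restricting lakes first and families first
#' give the same retained cells.
#'
#' @param species,lakes Input tables; inclusion filters are applied first.
#' @param config A [lakesize_config()].
#' @return List of class `"family_battery"`: `results` (data.frame:
#'   family, measure, predictor, n_lakes, slope, se, intercept, p,
#'   r_squared), `skipped` (named character vector of skip reasons).
#' @export
family_level_battery <- function(species, lakes,
                                 config = lakesize_config()) {
  flt <- apply_inclusion_filters(species, lakes, config)
  sp <- flt$species
  sp$S <- shell_size(sp$height, sp$width)
  area <- stats::setNames(log10(flt$lakes$area_km2), flt$lakes$lake_id)

  present_in <- tapply(sp$lake_id, sp$family,
                       function(l) length(unique(l)))
  rows <- list(); skipped <- character(0)
  for (fam in sort(names(present_in))) {
    if (present_in[[fam]] < config$family_min_lakes) {
      skipped[fam] <- sprintf("present in %d lakes (< %d)",
                              present_in[[fam]], config$family_min_lakes)
      next
    }
    fsp <- sp[sp$family == fam, , drop = FALSE]
    cells <- split(fsp$S, fsp$lake_id)
    cells <- cells[lengths(cells) >= 2]     # single-species cells lack a range
    if (length(cells) < 3) {
      skipped[fam] <- sprintf("%d lakes retain >= 2 species (< 3)",
                              length(cells))
      next
    }
    sm <- do.call(rbind, lapply(names(cells), function(l)
      fauna_size_summary(cells[[l]], l, mean_method = config$mean_method,
                         range_method = config$range_method)))
    pr <- data.frame(richness = log10(lengths(cells)),
                     area = unname(area[names(cells)]),
                     row.names = names(cells))
    for (m in c("S_range", "S_max", "S_min", "S_mean")) {
      y <- sm[[m]]; ok <- !is.na(y)
      for (p in c("richness", "area")) {
        if (sum(ok) < 3 || stats::var(pr[ok, p]) == 0) next
        if (stats::var(y[ok]) == 0) {
          # identical spectra everywhere: flat relationship, nothing to test
          rows[[paste(fam, m, p)]] <- data.frame(
            family = fam, measure = m, predictor = p, n_lakes = sum(ok),
            slope = 0, se = 0, intercept = y[ok][1], p = NA_real_,
            r_squared = 0, stringsAsFactors = FALSE)
          next
        }
        fit <- ols_fit(pr[ok, p, drop = FALSE], y[ok])
        cc <- fit$coefficients
        rows[[paste(fam, m, p)]] <- data.frame(
          family = fam, measure = m, predictor = p, n_lakes = sum(ok),
          slope = cc$estimate[2], se = cc$se[2],
          intercept = cc$estimate[1], p = cc$p[2],
          r_squared = fit$r_squared, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL,
                 skipped = skipped),
            class = "family_battery")
}

#' @export
print.family_battery <- function(x, digits = 3, ...) {
  if (is.null(x$results)) cat("No qualifying families.\n")
  else print(format(x$results, digits = digits), row.names = FALSE)
  if (length(x$skipped)) {
    cat("Skipped families:\n")
    for (f in names(x$skipped)) cat("  ", f, ": ", x$skipped[[f]], "\n", sep = "")
  }
  invisible(x)
}

#' Species longevity records
#'
#' Longevity is the stratigraphic duration of a species: oldest minus
#' youngest occurrence age (Ma), pooled across lakes. Records with dating
#' uncertainty above `config$age_uncertainty_max` (default 3 Myr) are
#' excluded; records without ages are dropped. Single-horizon species
#' (longevity 0) are retained.
#'
#' @param species Species table with `first_age`/`last_age` (Ma; first >=
#'   last) and optional `age_uncertainty`.
#' @param config A [lakesize_config()].
#' @return Data.frame: `species_id`, `longevity` (Myr), `S` (mm).
#' @export
longevity_records <- function(species, config = lakesize_config()) {
  sp <- species[!species$size_missing &
                !is.na(species$first_age) & !is.na(species$last_age), ,
                drop = FALSE]
  unc_ok <- is.na(sp$age_uncertainty) |
            sp$age_uncertainty <= config$age_uncertainty_max
  sp <- sp[unc_ok, , drop = FALSE]
  if (nrow(sp) == 0) stop("no dated, measured records remain")
  sp$S <- shell_size(sp$height, sp$width)
  agg_first <- tapply(sp$first_age, sp$species_id, max)
  agg_last <- tapply(sp$last_age, sp$species_id, min)
  agg_s <- tapply(sp$S, sp$species_id, max)
  ids <- names(agg_first)
  data.frame(species_id = ids,
             longevity = unname(agg_first[ids] - agg_last[ids]),
             S = unname(agg_s[ids]), stringsAsFactors = FALSE)
}

#' Regression of shell size on species longevity
#'
#' OLS of log10 S on longevity (Myr): does living longer as a species go
#' with a larger shell?
#'
#' @param records Data.frame from [longevity_records()] (>= 10 rows).
#' @return A `"lakesize_ols"` fit (response log10 S) with the records
#'   attached as attribute `"records"`.
#' @export
species_longevity_regression <- function(records) {
  if (nrow(records) < 10) stop("need at least 10 longevity records")
  if (all(records$longevity == 0)) stop("all longevities are zero")
  fit <- ols_fit(data.frame(longevity = records$longevity),
                 log10(records$S))
  attr(fit, "records") <- records
  fit
}

#' Horizon faunas: size measures at stratigraphic horizons
#'
#' Builds one fauna per (lake, horizon) cell from user-supplied horizon
#' labels and ages, and expresses time as the age of the lake at that
#' horizon (Myr since lake origin): `age_base - horizon_age`.
#'
#' @param species Species table with non-missing `horizon` and
#'   `horizon_age` for the records to use.
#' @param lakes Lake table with `age_base` (Ma of lake origin).
#' @param config A [lakesize_config()].
#' @return Data.frame: `lake_id`, `horizon`, `horizon_age` (Ma),
#'   `lake_age` (Myr since origin) and the four size measures.
#' @export
horizon_faunas <- function(species, lakes, config = lakesize_config()) {
  sp <- species[!species$size_missing & !is.na(species$horizon) &
                !is.na(species$horizon_age), , drop = FALSE]
  if (nrow(sp) == 0) stop("no records carry horizon assignments")
  base <- stats::setNames(lakes$age_base, lakes$lake_id)
  if (anyNA(base[unique(sp$lake_id)]))
    stop("age_base missing for lake(s): ",
         paste(unique(sp$lake_id)[is.na(base[unique(sp$lake_id)])],
               collapse = ", "))
  sp$S <- shell_size(sp$height, sp$width)
  key <- interaction(sp$lake_id, sp$horizon, drop = TRUE)
  rows <- lapply(split(sp, key), function(d) {
    sm <- fauna_size_summary(d$S, d$lake_id[1],
                             mean_method = config$mean_method,
                             range_method = config$range_method)
    sm$horizon <- d$horizon[1]
    sm$horizon_age <- d$horizon_age[1]
    sm$lake_age <- base[[d$lake_id[1]]] - d$horizon_age[1]
    sm
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (any(out$lake_age < -1e-9))
    stop("horizon older than lake origin for: ",
         paste(unique(out$lake_id[out$lake_age < 0]), collapse = ", "))
  out
}

#' Regressions of size measures on lake age
#'
#' OLS of each size measure of a horizon fauna on the age of the lake at
#' that horizon. A single contributing lake is allowed but flagged (no
#' between-lake replication).
#'
#' @param horizons Data.frame from [horizon_faunas()] (>= 3 rows).
#' @return Named list of `"lakesize_ols"` fits, one per size measure.
#' @export
lake_age_regressions <- function(horizons) {
  if (nrow(horizons) < 3) stop("need at least 3 horizon faunas")
  if (length(unique(horizons$lake_id)) == 1)
    warning("all horizons come from a single lake; no between-lake replication")
  fits <- list()
  for (m in c("S_range", "S_max", "S_min", "S_mean")) {
    y <- horizons[[m]]; ok <- !is.na(y)
    if (sum(ok) < 3) next
    fits[[m]] <- ols_fit(data.frame(lake_age = horizons$lake_age[ok]), y[ok])
  }
  if (!length(fits)) stop("no measure has 3 or more non-missing horizons")
  fits
}

#' Shell-size trend along clade ranks within a lineage
#'
#' Real node ages in these lineages are mostly unknown; the ordinal clade
#' rank (number of measurable speciation events from the lineage's first
#' species) stands in for evolutionary time. OLS of log10 S on clade rank.
#'
#' @param clade_rank Positive integer ranks (>= 3 distinct values).
#' @param s Shell sizes S (mm), same length.
#' @return A `"lakesize_ols"` fit (response log10 S, predictor rank).
#' @export
#' @examples
#' clade_rank_trend(1:5, c(5, 8, 11, 16, 22))
clade_rank_trend <- function(clade_rank, s) {
  if (length(clade_rank) != length(s)) stop("lengths differ")
  ok <- !is.na(clade_rank) & !is.na(s)
  clade_rank <- clade_rank[ok]; s <- s[ok]
  if (length(unique(clade_rank)) < 3)
    stop("need at least 3 distinct clade ranks")
  ols_fit(data.frame(clade_rank = clade_rank), log10(s))
}
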