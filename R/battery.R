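#' Assemble the per-lake predictor table
#'
#' Seven lake- and fauna-specific predictors, one row per lake: surface
#' area, mean family-level beta-Jaccard dissimilarity, distance to the
#' closest coeval lake, percent endemism, centroid latitude and longitude,
#' and species richness (measured species). Area, distance and richness
#' enter on the log10 scale by default (`config$log_predictors`); the
#' remaining predictors enter raw. Transformations are applied exactly
#' once, here.
#'
#' @param lakes Filtered lake table carrying `n_measured`
#'   ([apply_inclusion_filters()]); if an `n_measured` column is absent,
#'   `n_species` is used with a warning.
#' @param beta_means Named vector of per-lake mean beta-Jaccard values
#'   ([mean_beta_per_lake()]), or `NULL` to use the lake table's
#'   `avg_beta` column.
#' @param config A [lakesize_config()].
#' @return Data.frame with rownames = lake ids and columns `area`, `beta`,
#'   `distance`, `endemism`, `latitude`, `longitude`, `richness`.
#' @export
build_predictor_table <- function(lakes, beta_means = NULL,
                                  config = lakesize_config()) {
  rich <- if ("n_measured" %in% names(lakes)) lakes$n_measured else {
    warning("no n_measured column; using total species counts as richness")
    lakes$n_species
  }
  beta <- if (is.null(beta_means)) {
    if (!"avg_beta" %in% names(lakes) || anyNA(lakes$avg_beta))
      stop("no beta_means given and lake table lacks a complete avg_beta column")
    stats::setNames(lakes$avg_beta, lakes$lake_id)
  } else beta_means
  if (!all(lakes$lake_id %in% names(beta)))
    stop("beta means missing for: ",
         paste(setdiff(lakes$lake_id, names(beta)), collapse = ", "))
  out <- data.frame(
    area = lakes$area_km2,
    beta = unname(beta[lakes$lake_id]),
    distance = lakes$distance_km,
    endemism = lakes$pct_endemism,
    latitude = lakes$latitude,
    longitude = lakes$longitude,
    richness = rich,
    row.names = lakes$lake_id
  )
  for (p in config$log_predictors) out[[p]] <- log10(out[[p]])
  out
}

#' Run the full regression battery
#'
#' For each of the four fauna-level size measures (`S_range`, `S_max`,
#' `S_min`, `S_mean`): one multiple regression on all seven predictors
#' with hierarchical partitioning of independent contributions, plus seven
#' simple regressions (one per predictor). Mirrors the layout of the
#' study-style results table: per measure a model block (adjusted R^2, F,
#' P) and per predictor the multiple-regression slope, SE and P, the
#' independent contribution I (%), and the simple-regression slope, SE,
#' intercept, intercept SE, P and R^2.
#'
#' @param sizes Per-lake size measures ([fauna_size_table()]).
#' @param predictors Per-lake predictor table ([build_predictor_table()]).
#' @return List of class `"model_battery"`: `models` (one row per
#'   measure), `coefficients` (one row per measure x predictor), `n_lakes`.
#' @export
run_model_battery <- function(sizes, predictors) {
  measures <- c("S_range", "S_max", "S_min", "S_mean")
  preds <- names(predictors)
  ord <- match(sizes$lake_id, rownames(predictors))
  if (anyNA(ord))
    stop("predictor rows missing for: ",
         paste(sizes$lake_id[is.na(ord)], collapse = ", "))
  X <- predictors[ord, , drop = FALSE]

  models <- list(); rows <- list()
  for (m in measures) {
    y <- sizes[[m]]
    ok <- !is.na(y)
    if (sum(ok) < ncol(X) + 2)
      stop("fewer lakes (", sum(ok), ") than predictors + 2 for ", m)
    mfit <- ols_fit(X[ok, , drop = FALSE], y[ok])
    hp <- hier_part(X[ok, , drop = FALSE], y[ok])
    models[[m]] <- data.frame(measure = m, n = mfit$n,
                              adj_r_squared = mfit$adj_r_squared,
                              f_statistic = mfit$f_statistic,
                              p = mfit$model_p,
                              r_squared = mfit$r_squared)
    for (p in preds) {
      sfit <- ols_fit(X[ok, p, drop = FALSE], y[ok])
      mc <- mfit$coefficients[mfit$coefficients$term == p, ]
      sc <- sfit$coefficients
      rows[[paste(m, p)]] <- data.frame(
        measure = m, predictor = p,
        slope_mr = mc$estimate, se_mr = mc$se, p_mr = mc$p,
        i_pct = hp$partition$i_pct[hp$partition$predictor == p],
        slope = sc$estimate[2], se = sc$se[2],
        intercept = sc$estimate[1], intercept_se = sc$se[1],
        p = sc$p[2], r_squared = sfit$r_squared,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(models = do.call(rbind, c(models, make.row.names = FALSE)),
                 coefficients = do.call(rbind, c(rows, make.row.names = FALSE)),
                 n_lakes = nrow(X)),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, digits = 3, ...) {
  cat(sprintf("Regression battery over %d lakes\n", x$n_lakes))
  cat("Multiple-regression models:\n")
  print(format(x$models, digits = digits), row.names = FALSE)
  cat("Per-predictor results (multiple + simple regressions):\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Fit the shell-size predictor analysis
#'
#' The package's main entry point: applies the inclusion filters, computes
#' the shell-size estimator and the four log10 size measures per fauna,
#' builds the family-level beta-Jaccard predictor, screens
#' multicollinearity (VIF), and runs the full multiple/simple regression
#' battery with hierarchical partitioning. Optionally repeats the battery
#' with the Caspian fauna excluded (`config$exclude_caspian` controls
#' whether the *main* battery excludes it; the sensitivity rerun is always
#' attached when the named lake is present).
#'
#' @param species Species table ([read_species_table()]).
#' @param lakes Lake table ([read_lake_table()]).
#' @param config A [lakesize_config()].
#' @return Object of class `"lakesize_fit"` with elements `filtered`
#'   (species/lakes/report), `sizes`, `incidence`, `beta_matrix`,
#'   `beta_means`, `predictors`, `vif`, `battery`, `battery_no_caspian`
#'   (or `NULL`), `diagnostics` (pooled log10 S distribution), `config`.
#' @seealso [summary.lakesize_fit()], [resampling_test()]
#' @export
lakesize_fit <- function(species, lakes, config = lakesize_config()) {
  flt <- apply_inclusion_filters(species, lakes, config)
  sizes <- fauna_size_table(flt$species, config)
  inc <- family_incidence(flt$species, incidence_from = config$incidence_from)
  bmat <- beta_jaccard_matrix(inc)
  bmeans <- mean_beta_per_lake(bmat)
  preds <- build_predictor_table(flt$lakes, bmeans, config)

  drop_caspian <- function(p, s) {
    keep <- rownames(p) != config$caspian_id
    list(p = p[keep, , drop = FALSE], s = s[s$lake_id != config$caspian_id, ])
  }
  main <- if (config$exclude_caspian) drop_caspian(preds, sizes)
          else list(p = preds, s = sizes)
  battery <- run_model_battery(main$s, main$p)
  vifs <- vif(main$p)

  sensitivity <- NULL
  if (!config$exclude_caspian && config$caspian_id %in% rownames(preds) &&
      nrow(preds) >= ncol(preds) + 3) {
    nc <- drop_caspian(preds, sizes)
    sensitivity <- run_model_battery(nc$s, nc$p)
  }

  s_all <- shell_size(flt$species$height, flt$species$width)
  diag <- if (length(s_all) >= 3 && length(s_all) <= 5000 &&
              stats::sd(log10(s_all)) > 0) size_diagnostics(log10(s_all))
          else NULL

  structure(list(filtered = flt, sizes = sizes, incidence = inc,
                 beta_matrix = bmat, beta_means = bmeans,
                 predictors = main$p, vif = vifs, battery = battery,
                 battery_no_caspian = sensitivity, diagnostics = diag,
                 config = config),
            class = "lakesize_fit")
}

#' @export
print.lakesize_fit <- function(x, ...) {
  cat("Shell-size predictor analysis\n")
  cat(sprintf("  %d lakes, %d measured species\n",
              nrow(x$filtered$lakes), nrow(x$filtered$species)))
  if (!is.null(x$diagnostics)) print(x$diagnostics)
  cat(sprintf("  max VIF = %.2f (%s)\n", max(x$vif),
              names(x$vif)[which.max(x$vif)]))
  print(format(x$battery$models, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Summarise a fitted shell-size analysis
#'
#' @param object A `"lakesize_fit"`.
#' @param ... Unused.
#' @return `object`, invisibly, after printing the exclusion report, VIF
#'   screen and the full battery table.
#' @export
summary.lakesize_fit <- function(object, ...) {
  print(object$filtered$report)
  cat("VIF screen:\n"); print(round(object$vif, 2))
  print(object$battery)
  if (!is.null(object$battery_no_caspian)) {
    cat(sprintf("Sensitivity (excluding %s):\n", object$config$caspian_id))
    print(format(object$battery_no_caspian$models, digits = 3),
          row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.lakesize_fit <- function(object, ...) object$battery$coefficients

#' Diagnostic plots for a fitted shell-size analysis
#'
#' One panel per size measure: the measure against log10 species richness
#' with the simple-regression line — the dominant relationships of the
#' analysis.
#'
#' @param x A `"lakesize_fit"`.
#' @param predictor Predictor column to plot against (default
#'   `"richness"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lakesize_fit <- function(x, predictor = "richness", ...) {
  measures <- c("S_range", "S_max", "S_min", "S_mean")
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  px <- x$predictors[match(x$sizes$lake_id, rownames(x$predictors)), predictor]
  for (m in measures) {
    y <- x$sizes[[m]]
    ok <- !is.na(y)
    graphics::plot(px[ok], y[ok], xlab = predictor, ylab = paste(m, "(log10 mm)"),
                   main = m, pch = 19, ...)
    graphics::abline(stats::lm(y[ok] ~ px[ok]), lty = 2)
  }
  invisible(x)
}

#' Write the analysis result tables to a directory
#'
#' Emits the study-style outputs: `table2_replica.csv` (battery at 3
#' decimals), `table2_full_precision.csv`, `models.csv`, `vif.csv`,
#' `fauna_sizes.csv`, `beta_matrix.csv`, `beta_means.csv` and a JSON run
#' log recording the configuration (seed included).
#'
#' @param fit A `"lakesize_fit"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lakesize_results <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  disp <- fit$battery$coefficients
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, 3)
  utils::write.csv(disp, p("table2_replica.csv"), row.names = FALSE)
  utils::write.csv(fit$battery$coefficients, p("table2_full_precision.csv"),
                   row.names = FALSE)
  utils::write.csv(fit$battery$models, p("models.csv"), row.names = FALSE)
  utils::write.csv(data.frame(predictor = names(fit$vif), vif = fit$vif),
                   p("vif.csv"), row.names = FALSE)
  utils::write.csv(fit$sizes, p("fauna_sizes.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$beta_matrix), p("beta_matrix.csv"))
  utils::write.csv(data.frame(lake_id = names(fit$beta_means),
                              mean_beta = fit$beta_means),
                   p("beta_means.csv"), row.names = FALSE)
  log <- fit$config; class(log) <- NULL
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}
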