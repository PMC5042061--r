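# Builds a species table where family presence across lakes is controlled.
fam_dataset <- function() {
  lakes <- paste0("L", 1:7)
  sp <- list()
  for (i in seq_along(lakes)) {
    # Wide: 3 species in all 7 lakes; Narrow: only in the first 5 lakes;
    # Lonely: a single species per lake (no range -> cells dropped)
    n_wide <- 3 + i %% 2   # cell richness varies so it can be a predictor
    sp[[i]] <- data.frame(
      family = c(rep("Wide", n_wide), if (i <= 5) rep("Narrow", 2), "Lonely"),
      s = c(2, 4, 8 + i, seq_len(n_wide - 3), if (i <= 5) c(1, 3), 20))
  }
  rows <- do.call(rbind, lapply(seq_along(lakes), function(i)
    within(toy_species(setNames(list(sp[[i]]$s), lakes[i])),
           family <- sp[[i]]$family)))
  rows
}

test_that("family battery applies the more-than-five-lakes and two-species-cell filters", {
  species <- fam_dataset()
  lakes <- toy_lakes(paste0("L", 1:7))
  # some constructed cells fit exactly; silence summary.lm's note about that
  fb <- suppressWarnings(family_level_battery(species, lakes,
                                              lakesize_config(min_species = 4)))
  expect_true("Narrow" %in% names(fb$skipped))   # 5 lakes is not "more than five"
  expect_match(fb$skipped[["Narrow"]], "5 lakes")
  expect_true("Lonely" %in% names(fb$skipped))   # every cell has one species
  expect_setequal(unique(fb$results$family), "Wide")
  expect_true(all(fb$results$n_lakes == 7))
  expect_setequal(unique(fb$results$predictor), c("richness", "area"))
})

test_that("a family with identical size spectra everywhere shows flat regressions", {
  lakes <- toy_lakes(paste0("L", 1:6))
  species <- do.call(rbind, lapply(paste0("L", 1:6), function(l)
    toy_species(setNames(list(c(2, 5, 11, 17)), l))))
  fb <- family_level_battery(species, lakes, lakesize_config())
  area_rows <- fb$results[fb$results$predictor == "area", ]
  expect_true(all(area_rows$slope == 0))
  expect_true(all(area_rows$r_squared == 0))
})

test_that("longevity records subtract ages, pool across lakes and honour the dating cutoff", {
  sp <- toy_species(list(A = c(5, 7, 9), B = c(5, 2)))
  sp$species_id <- c("x", "y", "z", "x", "w")   # species x occurs in A and B
  sp$first_age <- c(15.0, 10, 8, 12, 6)
  sp$last_age <- c(13.8, 10, 8, 9, 6)
  sp$age_uncertainty <- c(1, 0.5, 5, 1, NA)
  rec <- longevity_records(sp, lakesize_config())
  rec <- rec[order(rec$species_id), ]
  # z excluded (uncertainty 5 > 3); w has unstated uncertainty and stays
  expect_setequal(rec$species_id, c("w", "x", "y"))
  expect_equal(rec$longevity[rec$species_id == "x"], 15.0 - 9)  # pooled min/max
  expect_equal(rec$longevity[rec$species_id == "y"], 0)         # retained at 0
  # longevity is invariant to row order
  rec2 <- longevity_records(sp[rev(seq_len(nrow(sp))), ], lakesize_config())
  expect_equal(rec2[order(rec2$species_id), ], rec, ignore_attr = TRUE)
})

test_that("the longevity regression reports the linear size association", {
  expect_error(species_longevity_regression(
    data.frame(species_id = "a", longevity = 1, S = 2)), "at least 10")
  set.seed(23)
  # no built-in dependence: adjusted R^2 should sit near zero
  rec <- data.frame(species_id = paste0("s", 1:500),
                    longevity = rexp(500, 1 / 2),
                    S = 10^rnorm(500, 0.5, 0.4))
  fit <- species_longevity_regression(rec)
  expect_lt(abs(fit$adj_r_squared), 0.02)
  # a planted dependence is recovered
  rec$S <- 10^(0.3 + 0.05 * rec$longevity + rnorm(500, sd = 0.1))
  fit2 <- species_longevity_regression(rec)
  b <- fit2$coefficients[2, ]
  expect_lt(abs(b$estimate - 0.05), 2.5 * b$se)
  expect_lt(fit2$model_p, 0.001)
})

test_that("horizon faunas convert horizon age to lake age and regress per measure", {
  lakes <- toy_lakes(c("A", "B"))
  lakes$age_base <- c(10, 8)
  sp <- toy_species(list(A = c(1, 4, 9, 2, 5, 16), B = c(2, 3, 4, 6)))
  sp$horizon <- c(rep("h1", 3), rep("h2", 3), rep("h1", 2), rep("h2", 2))
  sp$horizon_age <- c(rep(9.5, 3), rep(8, 3), rep(7, 2), rep(5, 2))
  hf <- horizon_faunas(sp, lakes, lakesize_config())
  expect_equal(nrow(hf), 4)
  expect_equal(sort(hf$lake_age), sort(c(10 - 9.5, 10 - 8, 8 - 7, 8 - 5)))
  fits <- suppressWarnings(lake_age_regressions(hf))  # 4 points: near-exact fits
  expect_true(all(c("S_mean", "S_max", "S_min") %in% names(fits)))
  # single-lake input runs with a warning
  hf_a <- hf[hf$lake_id == "A", ]
  extra <- hf_a[1, ]
  extra$lake_age <- extra$lake_age + 0.7
  extra[c("S_mean", "S_max", "S_min", "S_range")] <-
    extra[c("S_mean", "S_max", "S_min", "S_range")] + 0.05
  hf_a <- rbind(hf_a, extra)
  expect_warning(lake_age_regressions(hf_a), "single lake")
  expect_error(lake_age_regressions(hf[1:2, ]), "at least 3")
  # horizons predating the lake are impossible
  sp_bad <- sp; sp_bad$horizon_age[1:3] <- 12
  expect_error(horizon_faunas(sp_bad, lakes, lakesize_config()), "older")
})

test_that("a planted size increase with lake age is recovered", {
  set.seed(27)
  ages <- runif(40, 0, 5)
  hf <- data.frame(lake_id = rep(c("A", "B"), 20),
                   S_mean = 0.5 + 0.08 * ages + rnorm(40, sd = 0.05),
                   S_max = 1 + 0.1 * ages + rnorm(40, sd = 0.05),
                   S_min = 0.1 + rnorm(40, sd = 0.05),
                   S_range = 1 + 0.1 * ages + rnorm(40, sd = 0.05),
                   lake_age = ages)
  fits <- lake_age_regressions(hf)
  b <- fits$S_max$coefficients[2, ]
  expect_lt(abs(b$estimate - 0.1), 2.5 * b$se)
  b0 <- fits$S_min$coefficients[2, ]
  expect_gt(b0$p, 0.01)  # no trend planted for the minimum
})

test_that("clade-rank trends capture directional size change within lineages", {
  exact <- suppressWarnings(clade_rank_trend(1:5, 10^(0.2 * (1:5))))
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_gt(coef(exact)[2], 0)
  # overall increase with a final-stage decrease: positive slope, R^2 < 1
  dip <- clade_rank_trend(1:6, c(5, 8, 14, 22, 30, 18))
  expect_gt(coef(dip)[2], 0)
  expect_lt(dip$r_squared, 1)
  expect_error(clade_rank_trend(rep(2, 5), 1:5), "distinct")
  # permutation behaviour: shuffled sizes are rarely "significant"
  set.seed(29)
  s <- 10^rnorm(20, 0.5, 0.3)
  sig <- vapply(1:200, function(i)
    clade_rank_trend(1:20, sample(s))$coefficients$p[2] < 0.05, logical(1))
  expect_lt(mean(sig), 0.1)
})
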