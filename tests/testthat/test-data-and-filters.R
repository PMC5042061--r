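test_that("species CSV parsing keeps unsized rows flagged, not dropped", {
  f <- write_csv_lines(c(
    "species_id,lake_id,family,height,width",
    "sp1,A,Hydrobiidae,3.2,1.6",
    "sp2,A,Hydrobiidae,2.0,1.0",
    "sp3,A,Lymnaeidae,,",
    "sp4,B,Lymnaeidae,25,12",
    "sp5,B,Neritidae,6,5"))
  sp <- read_species_table(f)
  expect_equal(nrow(sp), 5)
  expect_equal(sum(sp$size_missing), 1)
  expect_equal(sp$species_id[sp$size_missing], "sp3")
})

test_that("an empty species file with a header parses to zero records", {
  f <- write_csv_lines("species_id,lake_id,family,height,width")
  expect_equal(nrow(read_species_table(f)), 0)
})

test_that("schema and cell-level problems are reported usefully", {
  # required column absent -> fatal naming the column
  f <- write_csv_lines(c("species_id,lake_id,family,width", "sp1,A,F,2"))
  expect_error(read_species_table(f), "height")
  # malformed numeric -> error carrying the file line number
  f <- write_csv_lines(c("species_id,lake_id,family,height,width",
                         "sp1,A,F,3.0,1.0",
                         "sp2,A,F,oops,1.0"))
  expect_error(read_species_table(f), "line.*3")
  # one of height/width blank is inconsistent, not size-missing
  f <- write_csv_lines(c("species_id,lake_id,family,height,width",
                         "sp1,A,F,3.0,"))
  expect_error(read_species_table(f), "height/width")
  # occurrence ages must decrease toward present (first >= last)
  f <- write_csv_lines(c("species_id,lake_id,family,height,width,first_age,last_age",
                         "sp1,A,F,3,1,2.0,5.0"))
  expect_error(read_species_table(f), "first_age")
})

test_that("lake table validation enforces log-transformability and uniqueness", {
  lk <- toy_lakes(c("A", "B"))
  f <- tempfile(fileext = ".csv")
  write_lakesize_table(lk, f)
  expect_silent(read_lake_table(f))
  bad <- lk; bad$area_km2[1] <- 0
  write_lakesize_table(bad, f)
  expect_error(read_lake_table(f), "area_km2")
  dup <- rbind(lk, lk[1, ])
  write_lakesize_table(dup, f)
  expect_error(read_lake_table(f), "duplicated")
})

test_that("species tables round-trip through write and re-read", {
  sp <- toy_species(list(A = c(1.37, 22.125, 3), B = c(0.8125, 5)))
  sp$first_age <- c(15.0, 14.2, NA, 3.317, 2)
  sp$last_age <- c(13.8, 14.2, NA, 1.5, 2)
  sp$endemic <- c(TRUE, FALSE, NA, TRUE, FALSE)
  f <- tempfile(fileext = ".csv")
  write_lakesize_table(sp, f)
  back <- read_species_table(f)
  for (col in c("species_id", "lake_id", "family", "endemic"))
    expect_identical(back[[col]], sp[[col]])
  for (col in c("height", "width", "first_age", "last_age"))
    expect_equal(back[[col]], sp[[col]], tolerance = 0)
})

test_that("inclusion filters drop unsized species and small faunas, with a faithful report", {
  sp <- toy_species(list(A = c(1, 2, 3, 4, 5), B = c(1, 2, 3), C = c(2, 4, 6, 8)))
  sp$size_missing[sp$species_id == "A_sp5"] <- TRUE  # A keeps 4 measured
  lk <- toy_lakes(c("A", "B", "C"))
  flt <- apply_inclusion_filters(sp, lk, lakesize_config())
  # B has 3 measured species -> excluded with its fauna
  expect_setequal(flt$lakes$lake_id, c("A", "C"))
  expect_equal(flt$lakes$n_measured, c(4L, 4L))
  expect_false(any(flt$species$lake_id == "B"))
  rp <- flt$report
  expect_equal(rp$n_species_unsized + rp$n_species_dropped_with_lake +
               rp$n_species_retained, rp$n_species_input)
  expect_equal(rp$n_lakes_excluded + rp$n_lakes_retained, rp$n_lakes_input)
})

test_that("filtering is idempotent and the all-valid case is the identity", {
  sp <- toy_species(list(A = 1:5, C = c(2, 4, 6, 8)))
  lk <- toy_lakes(c("A", "C"))
  once <- apply_inclusion_filters(sp, lk)
  expect_equal(once$species, sp, ignore_attr = TRUE)
  twice <- apply_inclusion_filters(once$species, once$lakes)
  expect_equal(twice$species, once$species)
  expect_equal(twice$lakes$lake_id, once$lakes$lake_id)
  expect_equal(twice$lakes$n_measured, once$lakes$n_measured)
})

test_that("filtering everything out is a fatal, diagnosed condition", {
  sp <- toy_species(list(A = c(1, 2)))
  expect_error(apply_inclusion_filters(sp, toy_lakes("A")), "no lake retains")
})

test_that("exclusion percentage matches the study's reported figure and guards its domain", {
  expect_equal(round(exclusion_percentage(22, 1412), 1), 1.6)
  expect_equal(exclusion_percentage(0, 100), 0)
  expect_equal(exclusion_percentage(50, 100), 50)
  expect_error(exclusion_percentage(1, 0), "positive")
  expect_error(exclusion_percentage(-1, 10))
  expect_error(exclusion_percentage(11, 10))
})

test_that("YAML configuration honours overrides and rejects unknown fields", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("fraction: 0.5", "repetitions: 200", "seed: 42"), f)
  cfg <- read_config_yaml(f)
  expect_equal(cfg$fraction, 0.5)
  expect_equal(cfg$repetitions, 200L)
  expect_equal(cfg$seed, 42L)
  expect_equal(cfg$min_species, 4L)  # untouched default
  writeLines("fractoin: 0.5", f)
  expect_error(read_config_yaml(f), "unknown configuration field")
  expect_error(lakesize_config(fraction = 0), "fraction")
})
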