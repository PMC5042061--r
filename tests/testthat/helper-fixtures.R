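# In-code fixture builders shared across test files.

# Species table from a named list of raw S vectors (one element per lake).
# Heights/widths are chosen so that sqrt(h * w) equals the given S exactly
# but h != w (exercises the estimator, not the identity case).
toy_species <- function(s_by_lake, family = "FamA") {
  rows <- lapply(names(s_by_lake), function(lk) {
    s <- s_by_lake[[lk]]
    data.frame(species_id = paste0(lk, "_sp", seq_along(s)),
               lake_id = lk, family = family,
               height = s * 2, width = s / 2,
               endemic = NA, first_age = NA_real_, last_age = NA_real_,
               age_uncertainty = NA_real_, lineage_id = NA_character_,
               clade_rank = NA_integer_, horizon = NA_character_,
               horizon_age = NA_real_, size_missing = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Minimal valid lake table for the given ids.
toy_lakes <- function(lake_ids, area = NULL, endemism = NULL) {
  n <- length(lake_ids)
  data.frame(lake_id = lake_ids,
             latitude = seq(38, 48, length.out = n),
             longitude = seq(5, 25, length.out = n),
             area_km2 = if (is.null(area)) 10^seq(1, 4, length.out = n) else area,
             duration_myr = rep(1, n),
             pct_endemism = if (is.null(endemism)) seq(0, 80, length.out = n) else endemism,
             distance_km = seq(5, 100, length.out = n),
             n_species = rep(10L, n),
             age_top = rep(1, n), age_base = rep(2, n),
             avg_beta = rep(0.5, n),
             stringsAsFactors = FALSE)
}

# Write a species CSV from raw field strings (for parser tests).
write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# All permutations of 1..k (ordering brute force for hierarchical
# partitioning oracles).
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1)) {
    for (pos in 0:(k - 1)) out[[length(out) + 1]] <- append(p, k, after = pos)
  }
  out
}
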