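#' Apply the study's inclusion filters
#'
#' Two filters define the analysed dataset: species without size
#' information are excluded (but counted), and lakes retaining fewer than
#' `config$min_species` measured species are excluded together with their
#' species. Species richness used downstream is always the count of
#' measured species per retained lake.
#'
#' Filtering is idempotent: applying it to its own output changes nothing.
#'
#' @param species Species table ([read_species_table()]).
#' @param lakes Lake table ([read_lake_table()]).
#' @param config A [lakesize_config()].
#' @return A list of class `"lakesize_filtered"` with elements `species`,
#'   `lakes` (the retained rows; `lakes` gains an `n_measured` column) and
#'   `report` (class `"exclusion_report"`: counts and percentages of
#'   exclusions at each step).
#' @export
apply_inclusion_filters <- function(species, lakes,
                                    config = lakesize_config()) {
  n_sp0 <- nrow(species)
  n_lk0 <- nrow(lakes)
  if (n_lk0 == 0) stop("empty lake table")

  unsized <- species$size_missing
  sized <- species[!unsized, , drop = FALSE]

  counts <- table(factor(sized$lake_id, levels = lakes$lake_id))
  keep_lake <- as.vector(counts) >= config$min_species
  lakes_kept <- lakes[keep_lake, , drop = FALSE]
  if (nrow(lakes_kept) == 0)
    stop("no lake retains >= ", config$min_species, " measured species; ",
         "largest measured fauna has ", max(counts), " species")
  lakes_kept$n_measured <- as.integer(counts[keep_lake])

  in_kept <- sized$lake_id %in% lakes_kept$lake_id
  species_kept <- sized[in_kept, , drop = FALSE]

  report <- structure(list(
    n_species_input = n_sp0,
    n_species_unsized = sum(unsized),
    pct_species_unsized = exclusion_percentage(sum(unsized), n_sp0),
    n_species_dropped_with_lake = sum(!in_kept),
    n_species_retained = nrow(species_kept),
    n_lakes_input = n_lk0,
    n_lakes_excluded = sum(!keep_lake),
    lakes_excluded = lakes$lake_id[!keep_lake],
    n_lakes_retained = nrow(lakes_kept),
    min_species = config$min_species
  ), class = "exclusion_report")

  structure(list(species = species_kept, lakes = lakes_kept,
                 report = report),
            class = "lakesize_filtered")
}

#' Percentage of excluded records
#'
#' @param n_excluded Number excluded (0 <= n_excluded <= n_total).
#' @param n_total Total number of records (> 0).
#' @return `100 * n_excluded / n_total` (unrounded).
#' @export
#' @examples
#' round(exclusion_percentage(22, 1412), 1)  # 1.6
exclusion_percentage <- function(n_excluded, n_total) {
  stopifnot(length(n_excluded) == 1, length(n_total) == 1)
  if (!is.finite(n_total) || n_total <= 0)
    stop("n_total must be positive")
  if (n_excluded < 0 || n_excluded > n_total)
    stop("n_excluded must lie in [0, n_total]")
  100 * n_excluded / n_total
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Inclusion filtering\n")
  cat(sprintf("  species: %d in, %d without size (%.1f%%), %d dropped with excluded lakes, %d retained\n",
              x$n_species_input, x$n_species_unsized, x$pct_species_unsized,
              x$n_species_dropped_with_lake, x$n_species_retained))
  cat(sprintf("  lakes:   %d in, %d below %d measured species, %d retained\n",
              x$n_lakes_input, x$n_lakes_excluded, x$min_species,
              x$n_lakes_retained))
  if (length(x$lakes_excluded))
    cat("  excluded lakes: ", paste(x$lakes_excluded, collapse = ", "), "\n")
  invisible(x)
}
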