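#' Read and validate a species table
#'
#' The species table holds one row per species occurrence in a lake, with
#' shell height and width in mm. Height and width may be blank (size
#' unknown); such rows are kept and flagged `size_missing` rather than
#' dropped, so exclusion counts can be reported downstream.
#'
#' Required columns: `species_id`, `lake_id`, `family`, `height`, `width`.
#' Optional columns: `endemic` (logical or 0/1: single-lake endemic),
#' `first_age`, `last_age` (Ma before present; first >= last),
#' `age_uncertainty` (Myr), `lineage_id`, `clade_rank` (positive integer),
#' `horizon`, `horizon_age` (Ma; stratigraphic horizon assignment).
#'
#' @param path Path to a UTF-8, comma-separated CSV with a header row and
#'   "." as decimal mark.
#' @return A data.frame with one row per record, typed columns, and a
#'   logical `size_missing` column.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species_id,lake_id,family,height,width",
#'              "sp1,A,Hydrobiidae,3.2,1.6",
#'              "sp2,A,Lymnaeidae,,"), f)
#' read_species_table(f)
read_species_table <- function(path) {
  raw <- read_table_raw(path, required = c("species_id", "lake_id", "family",
                                           "height", "width"))
  out <- data.frame(
    species_id = as.character(raw$species_id),
    lake_id = as.character(raw$lake_id),
    family = as.character(raw$family),
    height = parse_num(raw, "height", positive = TRUE),
    width = parse_num(raw, "width", positive = TRUE),
    stringsAsFactors = FALSE
  )
  nr <- nrow(out)
  out$endemic <- if ("endemic" %in% names(raw)) parse_bool(raw, "endemic")
                 else rep(NA, nr)
  for (col in c("first_age", "last_age", "age_uncertainty", "horizon_age"))
    out[[col]] <- if (col %in% names(raw))
      parse_num(raw, col, nonneg = TRUE) else rep(NA_real_, nr)
  out$lineage_id <- if ("lineage_id" %in% names(raw))
    as.character(raw$lineage_id) else rep(NA_character_, nr)
  out$clade_rank <- if ("clade_rank" %in% names(raw))
    parse_num(raw, "clade_rank", positive = TRUE, integer = TRUE)
    else rep(NA_integer_, nr)
  out$horizon <- if ("horizon" %in% names(raw))
    as.character(raw$horizon) else rep(NA_character_, nr)

  # a record either carries both measurements or is flagged size-missing
  half <- xor(is.na(out$height), is.na(out$width))
  if (any(half))
    stop("rows with exactly one of height/width present (lines ",
         paste(which(half) + 1L, collapse = ", "), ")")
  out$size_missing <- is.na(out$height)

  both <- !is.na(out$first_age) & !is.na(out$last_age)
  bad <- both & out$first_age < out$last_age
  if (any(bad))
    stop("first_age < last_age (ages are Ma before present, first is the ",
         "older occurrence) at lines ", paste(which(bad) + 1L, collapse = ", "))
  out
}

#' Read and validate a lake table
#'
#' One row per lake with physiographic and faunal descriptors: centroid
#' coordinates, surface area (km^2), duration (Myr), percentage of
#' single-lake endemics, distance to the closest coeval lake (km), and the
#' total species count. Area and distance must be strictly positive (they
#' are log10-transformed downstream).
#'
#' Required columns: `lake_id`, `latitude`, `longitude`, `area_km2`,
#' `duration_myr`, `pct_endemism`, `distance_km`, `n_species`. Optional:
#' `age_top`, `age_base` (Ma), `avg_beta`.
#'
#' @param path Path to a CSV file (see [read_species_table()] for dialect).
#' @return A validated data.frame with one row per lake.
#' @export
read_lake_table <- function(path) {
  raw <- read_table_raw(path, required = c("lake_id", "latitude", "longitude",
                                           "area_km2", "duration_myr",
                                           "pct_endemism", "distance_km",
                                           "n_species"))
  out <- data.frame(
    lake_id = as.character(raw$lake_id),
    latitude = parse_num(raw, "latitude"),
    longitude = parse_num(raw, "longitude"),
    area_km2 = parse_num(raw, "area_km2", positive = TRUE, required = TRUE),
    duration_myr = parse_num(raw, "duration_myr", positive = TRUE,
                             required = TRUE),
    pct_endemism = parse_num(raw, "pct_endemism", nonneg = TRUE,
                             required = TRUE),
    distance_km = parse_num(raw, "distance_km", positive = TRUE,
                            required = TRUE),
    n_species = parse_num(raw, "n_species", nonneg = TRUE, integer = TRUE,
                          required = TRUE),
    stringsAsFactors = FALSE
  )
  for (col in c("age_top", "age_base", "avg_beta"))
    out[[col]] <- if (col %in% names(raw)) parse_num(raw, col) else NA_real_
  dup <- duplicated(out$lake_id)
  if (any(dup))
    stop("duplicated lake_id: ", paste(unique(out$lake_id[dup]), collapse = ", "))
  if (any(out$pct_endemism > 100))
    stop("pct_endemism above 100 for: ",
         paste(out$lake_id[out$pct_endemism > 100], collapse = ", "))
  out
}

#' The bundled table of 23 Miocene-to-recent European long-lived lakes
#'
#' Returns the study's lake-level input: 23 lakes with centroid coordinates,
#' surface area, duration, percent endemism, distance to the closest coeval
#' lake, species count over the whole duration, and the average family-level
#' beta-Jaccard dissimilarity per lake.
#'
#' @return A data.frame as from [read_lake_table()].
#' @export
#' @examples
#' lakes <- study_lakes()
#' cor(lakes$pct_endemism, log10(lakes$n_species))
study_lakes <- function() {
  read_lake_table(system.file("extdata", "lakes_table.csv",
                              package = "lakesize", mustWork = TRUE))
}

# -- internal parsing helpers -------------------------------------------------

read_table_raw <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8",
                         na.strings = c("", "NA"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("required column(s) missing from ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  raw
}

# numeric parser with row-level (line-numbered) error reporting; the +1
# offsets the header row so line numbers match the file
parse_num <- function(raw, col, positive = FALSE, nonneg = FALSE,
                      integer = FALSE, required = FALSE) {
  x <- raw[[col]]
  v <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(v)
  if (any(bad))
    stop("malformed numeric in column '", col, "' at line(s) ",
         paste(which(bad) + 1L, collapse = ", "),
         " (value(s): ", paste(x[bad], collapse = ", "), ")")
  if (required && anyNA(v))
    stop("missing value in required column '", col, "' at line(s) ",
         paste(which(is.na(v)) + 1L, collapse = ", "))
  if (positive && any(v <= 0, na.rm = TRUE))
    stop("non-positive value in column '", col, "' at line(s) ",
         paste(which(!is.na(v) & v <= 0) + 1L, collapse = ", "))
  if (nonneg && any(v < 0, na.rm = TRUE))
    stop("negative value in column '", col, "' at line(s) ",
         paste(which(!is.na(v) & v < 0) + 1L, collapse = ", "))
  if (integer) {
    if (any(v != floor(v), na.rm = TRUE))
      stop("non-integer value in column '", col, "' at line(s) ",
           paste(which(!is.na(v) & v != floor(v)) + 1L, collapse = ", "))
    v <- as.integer(v)
  }
  v
}

parse_bool <- function(raw, col) {
  x <- tolower(raw[[col]])
  v <- rep(NA, length(x))
  v[x %in% c("true", "t", "1", "yes")] <- TRUE
  v[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & is.na(v)
  if (any(bad))
    stop("malformed logical in column '", col, "' at line(s) ",
         paste(which(bad) + 1L, collapse = ", "))
  v
}

#' Write a species or lake table back to CSV
#'
#' Round-trip companion to the readers: text columns are written verbatim
#' and numerics at full precision, so reading the file back reproduces the
#' table.
#'
#' @param x A data.frame from [read_species_table()] or [read_lake_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lakesize_table <- function(x, path) {
  x <- x[setdiff(names(x), "size_missing")]
  utils::write.csv(format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
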