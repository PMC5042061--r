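#' Family incidence matrix
#'
#' Builds the lakes x families presence/absence matrix underlying the
#' compositional dissimilarity predictor. A cell is 1 when at least one
#' (by default, measured) species of that family occurs in that lake.
#'
#' @param species Species table; a `size_missing` column is honoured when
#'   `incidence_from = "measured"`.
#' @param incidence_from `"measured"` (default) or `"all"` records.
#' @param missing_family `"drop"` (default) silently drops records without
#'   a family label; `"error"` stops.
#' @return Integer 0/1 matrix, rows = lakes, columns = families.
#' @export
family_incidence <- function(species,
                             incidence_from = c("measured", "all"),
                             missing_family = c("drop", "error")) {
  incidence_from <- match.arg(incidence_from)
  missing_family <- match.arg(missing_family)
  if (incidence_from == "measured" && "size_missing" %in% names(species))
    species <- species[!species$size_missing, , drop = FALSE]
  no_fam <- is.na(species$family) | species$family == ""
  if (any(no_fam)) {
    if (missing_family == "error")
      stop(sum(no_fam), " record(s) without family label")
    species <- species[!no_fam, , drop = FALSE]
  }
  if (nrow(species) == 0) stop("no records with family labels")
  tab <- table(species$lake_id, species$family)
  m <- matrix(as.integer(tab > 0), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Jaccard dissimilarity between two family sets
#'
#' \eqn{\beta_{jac} = (b + c) / (a + b + c)} where a is the number of
#' shared families and b, c the numbers unique to each fauna: 0 for
#' identical composition, 1 for none shared.
#'
#' @param a,b Character vectors (sets) of family names; at least one
#'   non-empty.
#' @return Dissimilarity in \[0, 1\].
#' @export
#' @examples
#' jaccard_dissimilarity(c("F1", "F2", "F3"), c("F1", "F4"))  # 0.75
jaccard_dissimilarity <- function(a, b) {
  a <- unique(a[!is.na(a)]); b <- unique(b[!is.na(b)])
  u <- length(union(a, b))
  if (u == 0) stop("Jaccard dissimilarity undefined for two empty sets")
  1 - length(intersect(a, b)) / u
}

#' Pairwise beta-Jaccard matrix across lakes
#'
#' @param incidence 0/1 matrix from [family_incidence()] (>= 2 lakes; no
#'   all-zero rows).
#' @return Symmetric matrix of \eqn{\beta_{jac}} with zero diagonal.
#' @export
beta_jaccard_matrix <- function(incidence) {
  if (nrow(incidence) < 2) stop("need at least 2 lakes")
  if (any(rowSums(incidence) == 0))
    stop("all-zero incidence row(s): ",
         paste(rownames(incidence)[rowSums(incidence) == 0], collapse = ", "))
  inc <- incidence > 0
  shared <- tcrossprod(inc * 1)               # a
  tot <- rowSums(inc)
  uni <- outer(tot, tot, "+") - shared        # a + b + c
  m <- 1 - shared / uni
  diag(m) <- 0
  dimnames(m) <- list(rownames(incidence), rownames(incidence))
  m
}

#' Mean beta-Jaccard per lake
#'
#' The compositional predictor entering the regressions: each lake's
#' arithmetic mean of its pairwise dissimilarities to all other lakes.
#'
#' @param beta Symmetric dissimilarity matrix with zero diagonal
#'   ([beta_jaccard_matrix()]).
#' @return Named numeric vector of per-lake means.
#' @export
mean_beta_per_lake <- function(beta) {
  n <- nrow(beta)
  if (is.null(n) || n < 2) stop("need at least 2 lakes")
  if (!isTRUE(all.equal(beta, t(beta))))
    stop("dissimilarity matrix must be symmetric")
  rowSums(beta) / (n - 1)
}
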