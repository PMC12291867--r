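# Pairwise predictor distances: great-circle, vertical, and the scaled
# environmental dissimilarity with its 0.001 floor.

EARTH_RADIUS_M <- 6371008.8  # mean Earth radius; haversine on a sphere

#' Great-circle distance matrix between sampling sites
#'
#' Haversine distances on a sphere of mean radius 6 371 008.8 m. At the
#' scale of a regional survey the deviation from ellipsoidal geodesics is
#' below 0.5% and immaterial relative to positional uncertainty.
#'
#' @param sites Site table with `site_id`, `longitude`, `latitude` (degrees).
#' @return A `dissim_matrix` in metres (zero diagonal).
#' @export
geodesic_distance_matrix <- function(sites) {
  sites <- validate_sites(tibble::as_tibble(sites))
  p <- as.matrix(sites[, c("longitude", "latitude")])
  d <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_M))
  dimnames(d) <- list(sites$site_id, sites$site_id)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dissim_matrix(d, metric = "geodesic_m")
}

#' Altitude (vertical) distance matrix
#'
#' @param sites Site table with `site_id` and `altitude` (metres).
#' @return A `dissim_matrix` of absolute altitude differences in metres.
#' @export
altitude_distance_matrix <- function(sites) {
  sites <- validate_sites(tibble::as_tibble(sites))
  d <- abs(outer(sites$altitude, sites$altitude, "-"))
  dimnames(d) <- list(sites$site_id, sites$site_id)
  dissim_matrix(d, metric = "altitude_m")
}

#' Scaled environmental dissimilarity with a 0.001 floor
#'
#' Pairwise Euclidean distance between site environmental vectors, divided
#' by the maximum pairwise distance in the matrix, plus 0.001:
#' `Ed_ij = Euc_ij / max(Euc) + 0.001`. The additive floor keeps
#' environmentally identical pairs distinguishable from structural zeros, so
#' all values lie in `[0.001, 1.001]` and the most dissimilar pair maps to
#' exactly 1.001. The maximum is taken within the variable group passed in,
#' so each predictor group (physicochemical, land-use proportions, ...) is
#' scaled independently.
#'
#' @param env Data frame: `site_id` plus numeric variables (one group).
#' @param standardize z-score each variable first (default `TRUE`, preventing
#'   unit dominance; recorded in the output metadata).
#' @return A `dissim_matrix`, diagonal = 0.001 (the formula applied to
#'   self-pairs; excluded from pairwise analyses downstream).
#' @export
env_dissimilarity <- function(env, standardize = TRUE) {
  env <- tibble::as_tibble(env)
  if (!"site_id" %in% names(env)) names(env)[1] <- "site_id"
  ids <- as.character(env$site_id)
  m <- as.matrix(env[setdiff(names(env), c("site_id", "month", "region"))])
  if (nrow(m) < 2) abort("need at least 2 sites")
  if (anyNA(m) || !all(is.finite(m))) abort("environmental values must be finite")
  if (standardize) {
    s <- apply(m, 2, sd)
    if (any(s == 0))
      abort(paste0("zero spread in variable(s): ",
                   paste(colnames(m)[s == 0], collapse = ", "),
                   "; cannot standardize"))
    m <- scale(m)
  }
  euc <- as.matrix(dist(m))
  emax <- max(euc)
  if (emax == 0) abort("all pairwise Euclidean distances are zero")
  ed <- euc / emax + 0.001
  dimnames(ed) <- list(ids, ids)
  dissim_matrix(ed, metric = "env_dissimilarity",
                meta = list(standardized = standardize, euc_max = emax))
}
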