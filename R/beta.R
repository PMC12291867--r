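# Baselga-family beta-diversity partitioning.
#
# Incidence: beta_sor = (b+c)/(2a+b+c) splits into turnover
#   beta_sim = min(b,c)/(a+min(b,c)) and nestedness beta_nes = beta_sor-beta_sim.
# Abundance: d_BC = (B+C)/(2A+B+C) with A = sum_k min(x_ik, x_jk) splits into
#   balanced variation d_BC_bal = min(B,C)/(A+min(B,C)) and abundance
#   gradient d_BC_gra = d_BC - d_BC_bal.
# Multi-site versions replace per-pair ratios with ratios of sums over all
# unordered pairs; at N = 2 they reduce exactly to the pairwise values.

pair_abc <- function(m) {
  # abundance components A, B, C for every unordered pair (matrices)
  n <- nrow(m)
  A <- B <- C <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      a <- sum(pmin(xi, m[j, ]))
      A[i, j] <- A[j, i] <- a
      B[i, j] <- B[j, i] <- sum(xi) - a
      C[i, j] <- C[j, i] <- sum(m[j, ]) - a
    }
  }
  list(A = A, B = B, C = C)
}

beta_from_abc <- function(A, B, C) {
  tot <- 2 * A + B + C
  total <- ifelse(tot == 0, NA_real_, (B + C) / tot)
  mn <- pmin(B, C)
  turn <- ifelse(A + mn == 0 & tot > 0, 1,
                 ifelse(tot == 0, NA_real_, mn / (A + mn)))
  # both-empty pairs undefined; one-empty pairs: total = 1, turnover NA
  one_empty <- (A + B == 0) != (A + C == 0)
  turn[one_empty] <- NA_real_
  nest <- total - turn
  list(total = total, turnover = turn, nestedness = nest)
}

#' Pairwise Sorensen dissimilarity partitioned into turnover and nestedness
#'
#' Presence/absence partitioning: total dissimilarity `beta_sor`, species
#' turnover `beta_sim`, and nestedness-resultant `beta_nes = beta_sor -
#' beta_sim`.
#'
#' @param cm A community matrix (or coercible data frame); counts are
#'   reduced to incidences.
#' @return A `dissim_matrix` (values = `beta_sor`) with components
#'   `beta_sor`, `beta_sim`, `beta_nes`.
#' @examples
#' cm <- community_matrix(data.frame(site_id = c("u", "v"),
#'                                   A = c(1, 0), B = c(1, 1), C = c(1, 1),
#'                                   D = c(0, 1)))
#' tidy(pairwise_sorensen(cm))  # beta_sor = 1/3, all of it turnover
#' @export
pairwise_sorensen <- function(cm) {
  cm <- as_community_matrix(cm)
  p <- pair_abc((unclass(cm) > 0) * 1)
  b <- beta_from_abc(p$A, p$B, p$C)
  diag(b$total) <- diag(b$turnover) <- diag(b$nestedness) <- 0
  dissim_matrix(b$total, metric = "beta_sor",
                components = list(beta_sor = b$total, beta_sim = b$turnover,
                                  beta_nes = b$nestedness))
}

#' Pairwise Bray-Curtis dissimilarity partitioned into balanced variation
#' and abundance gradient
#'
#' Abundance-based analogue of [pairwise_sorensen()]: `d_BC` splits into the
#' balanced-variation component `d_BC_bal` (abundance turnover) and the
#' abundance-gradient component `d_BC_gra` (abundance nestedness). On a 0/1
#' matrix it coincides with the Sorensen partition.
#'
#' @inheritParams pairwise_sorensen
#' @return A `dissim_matrix` (values = `d_BC`) with components `d_BC`,
#'   `d_BC_bal`, `d_BC_gra`.
#' @export
pairwise_braycurtis <- function(cm) {
  cm <- as_community_matrix(cm)
  p <- pair_abc(unclass(cm))
  b <- beta_from_abc(p$A, p$B, p$C)
  diag(b$total) <- diag(b$turnover) <- diag(b$nestedness) <- 0
  dissim_matrix(b$total, metric = "d_BC",
                components = list(d_BC = b$total, d_BC_bal = b$turnover,
                                  d_BC_gra = b$nestedness))
}

multisite_from_abc <- function(A, B, C, labels) {
  ut <- upper.tri(A)
  sA <- sum(A[ut]); smin <- sum(pmin(B, C)[ut]); smax <- sum(pmax(B, C)[ut])
  total <- (smin + smax) / (2 * sA + smin + smax)
  turnover <- smin / (sA + smin)
  out <- tibble::tibble(total = total, turnover = turnover,
                        nestedness = total - turnover)
  names(out) <- labels
  out
}

#' Multi-site Sorensen dissimilarity and its partition
#'
#' A single incidence-based dissimilarity over all N sites (not an average
#' of pairwise values), partitioned into turnover (`beta_SIM`) and
#' nestedness (`beta_SNE`) following the sums-over-pairs formulation: with
#' `b_ij` the number of taxa present at site i but not j,
#' `beta_SIM = Smin / (K + Smin)` and
#' `beta_SOR = (Smin + Smax) / (2K + Smin + Smax)`, where
#' `Smin = sum min(b_ij, b_ji)`, `Smax = sum max(b_ij, b_ji)` over unordered
#' pairs and `K = sum_i S_i - S_T` (site richnesses minus pooled richness).
#'
#' @inheritParams pairwise_sorensen
#' @return One-row tibble: `beta_SOR`, `beta_SIM`, `beta_SNE`.
#' @export
multisite_sorensen <- function(cm) {
  cm <- as_community_matrix(cm)
  m <- (unclass(cm) > 0) * 1
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) < 2) abort("multi-site index needs at least 2 non-empty sites")
  p <- pair_abc(m)
  ut <- upper.tri(p$B)
  smin <- sum(pmin(p$B, p$C)[ut]); smax <- sum(pmax(p$B, p$C)[ut])
  # K counts each taxon's surplus occupancy once (not per pair): sum of site
  # richnesses minus pooled richness
  K <- sum(m) - sum(colSums(m) > 0)
  total <- (smin + smax) / (2 * K + smin + smax)
  turnover <- smin / (K + smin)
  tibble::tibble(beta_SOR = total, beta_SIM = turnover,
                 beta_SNE = total - turnover)
}

#' Multi-site Bray-Curtis dissimilarity and its partition
#'
#' Abundance analogue of [multisite_sorensen()]: `beta_BC` partitioned into
#' balanced variation (`beta_BC_BAL`) and abundance gradient
#' (`beta_BC_GRA`), computed from the sums of per-pair shared abundance `A`
#' and excesses `B`, `C` over all unordered pairs.
#'
#' @inheritParams pairwise_sorensen
#' @return One-row tibble: `beta_BC`, `beta_BC_BAL`, `beta_BC_GRA`.
#' @export
multisite_braycurtis <- function(cm) {
  cm <- as_community_matrix(cm)
  m <- unclass(cm)[rowSums(unclass(cm)) > 0, , drop = FALSE]
  if (nrow(m) < 2) abort("multi-site index needs at least 2 non-empty sites")
  p <- pair_abc(m)
  multisite_from_abc(p$A, p$B, p$C, c("beta_BC", "beta_BC_BAL", "beta_BC_GRA"))
}

#' Group-wise summary of a partitioned pairwise dissimilarity matrix
#'
#' For each group (e.g. region x month, or the whole survey) reports the
#' number of within-group site pairs, mean dissimilarity, mean similarity
#' (1 - dissimilarity), mean turnover and nestedness components, and the
#' turnover share of total dissimilarity. Pairs with undefined components
#' (an empty site, if admitted) are dropped with a warning.
#'
#' @param dm A `dissim_matrix` with partition components (from
#'   [pairwise_sorensen()] or [pairwise_braycurtis()]).
#' @param groups Optional data frame `site_id`, `group`; sites sharing a
#'   label are summarized together. `NULL` = one group of all sites.
#' @return Tibble: `group`, `n_sites`, `n_pairs`, `mean_dissimilarity`,
#'   `mean_similarity`, `mean_turnover`, `mean_nestedness`,
#'   `turnover_fraction`.
#' @export
component_summary <- function(dm, groups = NULL) {
  comps <- attr(dm, "components")
  if (is.null(comps)) abort("dissimilarity matrix has no partition components")
  long <- tidy(dm)
  cn <- names(comps)  # total, turnover, nestedness order
  if (is.null(groups)) {
    groups <- tibble::tibble(site_id = rownames(dm), group = "all")
  }
  groups <- tibble::as_tibble(groups)
  out <- purrr::map_dfr(split(groups$site_id, groups$group), function(ids) {
    if (length(ids) < 2) {
      warn("group with fewer than 2 sites skipped")
      return(NULL)
    }
    sub <- dplyr::filter(long, .data$site_i %in% ids, .data$site_j %in% ids)
    if (anyNA(sub[[cn[2]]])) {
      warn(paste(sum(is.na(sub[[cn[2]]])),
                 "pair(s) with undefined components dropped"))
      sub <- sub[!is.na(sub[[cn[2]]]), ]
    }
    tibble::tibble(
      n_sites = length(ids), n_pairs = nrow(sub),
      mean_dissimilarity = mean(sub[[cn[1]]]),
      mean_similarity = 1 - mean(sub[[cn[1]]]),
      mean_turnover = mean(sub[[cn[2]]]),
      mean_nestedness = mean(sub[[cn[3]]]),
      turnover_fraction = mean(sub[[cn[2]]]) / mean(sub[[cn[1]]]))
  }, .id = "group")
  out
}
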