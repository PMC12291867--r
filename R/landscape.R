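# Circular-buffer landscape analysis: class composition plus the
# landscape-level pattern metrics LPI, CONTAG, SHDI (FRAGSTATS
# conventions: 8-neighbour patches, 4-neighbour double-counted
# adjacencies) and the human-activity intensity index HAILS.

#' Cells inside a circular buffer
#'
#' Logical mask of grid cells whose centre lies within `radius` metres of
#' the site point (centre-in-circle rule; boundary cells are not
#' area-weighted).
#'
#' @param grid A `landuse_grid`.
#' @param site One-row data frame or list with metric coordinates `x`, `y`
#'   (same CRS as the grid origin).
#' @param radius Buffer radius in metres; must be at least one cell size.
#' @return Logical matrix, `TRUE` inside the buffer. A warning is issued if
#'   the buffer extends beyond the grid (partial buffer).
#' @export
extract_buffer <- function(grid, site, radius) {
  if (radius < grid$cellsize)
    abort("radius smaller than the cell size gives an empty/ambiguous buffer")
  cc <- cell_centres(grid)
  if (site$x < grid$xll || site$y < grid$yll ||
      site$x > grid$xll + ncol(grid$codes) * grid$cellsize ||
      site$y > grid$yll + nrow(grid$codes) * grid$cellsize)
    abort("site lies outside the grid")
  dx2 <- (cc$x - site$x)^2
  dy2 <- (cc$y - site$y)^2
  mask <- outer(dy2, dx2, "+") <= radius^2
  if (site$x - radius < grid$xll || site$y - radius < grid$yll ||
      site$x + radius > grid$xll + ncol(grid$codes) * grid$cellsize ||
      site$y + radius > grid$yll + nrow(grid$codes) * grid$cellsize)
    warn("buffer extends beyond the grid; metrics use the partial buffer")
  mask
}

#' Land-use class proportions within a buffer mask
#'
#' @param grid A `landuse_grid`.
#' @param mask Logical mask from [extract_buffer()].
#' @return Named numeric vector over all grid classes (zeros included),
#'   summing to 1 over non-NODATA masked cells.
#' @export
landuse_proportions <- function(grid, mask) {
  v <- grid$codes[mask]
  v <- v[!is.na(v)]
  if (!length(v)) abort("no data cells inside the buffer")
  counts <- tabulate(match(v, grid$classes), nbins = length(grid$classes))
  stats::setNames(counts / length(v), names(grid$classes))
}

#' Label patches (connected same-class components) within a mask
#'
#' 8-neighbour connectivity, the FRAGSTATS patch convention.
#'
#' @inheritParams landuse_proportions
#' @return Integer matrix of patch ids (NA outside mask / NODATA).
#' @export
patch_label <- function(grid, mask) {
  m <- grid$codes
  nr <- nrow(m); nc <- ncol(m)
  inmask <- mask & !is.na(m)
  idx <- which(inmask)
  lab <- matrix(NA_integer_, nr, nc)
  if (!length(idx)) return(lab)
  # same-class edges between each cell and its E, S, SE, SW neighbours
  r <- ((idx - 1) %% nr) + 1; cl <- ((idx - 1) %/% nr) + 1
  edges <- list()
  for (d in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    r2 <- r + d[1]; c2 <- cl + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- (c2[ok] - 1) * nr + r2[ok]
    i <- idx[ok]
    keep <- inmask[j] & m[i] == m[j]
    edges[[length(edges) + 1]] <- cbind(i[keep], j[keep])
  }
  e <- do.call(rbind, edges)
  if (is.null(e) || nrow(e) == 0) {
    lab[idx] <- seq_along(idx)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(
    cbind(match(e[, 1], idx), match(e[, 2], idx)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

#' Largest Patch Index
#'
#' Share (%) of the buffer occupied by the single largest patch.
#'
#' @param patches Patch id matrix from [patch_label()].
#' @return LPI in (0, 100].
#' @export
metric_lpi <- function(patches) {
  sizes <- table(patches[!is.na(patches)])
  if (!length(sizes)) abort("no patches in mask")
  100 * max(sizes) / sum(sizes)
}

#' Shannon's Diversity Index of class proportions
#'
#' @param proportions Named proportions summing to 1 (zeros allowed).
#' @return `-sum(p * log(p))` over classes with `p > 0`.
#' @export
metric_shdi <- function(proportions) {
  p <- proportions[proportions > 0]
  -sum(p * log(p))
}

# double-counted 4-neighbour adjacency matrix g[i, k] within the mask
adjacency_counts <- function(grid, mask) {
  m <- grid$codes
  nr <- nrow(m); nc <- ncol(m)
  inmask <- mask & !is.na(m)
  k <- length(grid$classes)
  g <- matrix(0, k, k, dimnames = list(names(grid$classes),
                                       names(grid$classes)))
  add_pairs <- function(a_idx, b_idx) {
    ok <- inmask[a_idx] & inmask[b_idx]
    if (!any(ok)) return()
    ca <- match(m[a_idx[ok]], grid$classes)
    cb <- match(m[b_idx[ok]], grid$classes)
    # double count: one tabulation per direction
    cnt <- tabulate((ca - 1) * k + cb, nbins = k * k) +
      tabulate((cb - 1) * k + ca, nbins = k * k)
    g <<- g + matrix(cnt, k, k, byrow = TRUE)
  }
  # horizontal neighbours
  if (nc > 1) {
    a <- as.vector(outer(seq_len(nr), seq_len(nc - 1) - 1, function(r, c0) r + c0 * nr))
    add_pairs(a, a + nr)
  }
  if (nr > 1) {
    a <- as.vector(outer(seq_len(nr - 1), seq_len(nc) - 1, function(r, c0) r + c0 * nr))
    add_pairs(a, a + 1)
  }
  g
}

#' Contagion Index
#'
#' Aggregation of the class mosaic within the mask, in percent:
#' `CONTAG = (1 + sum_ik P*_ik ln P*_ik / (2 ln m)) * 100`, where
#' `P*_ik = P_i * g_ik / sum_k' g_ik'`, `g_ik` are double-counted
#' 4-neighbour adjacencies, `P_i` class proportions, and `m` the number of
#' classes present. A single-class mask is defined as maximum contagion
#' (100).
#'
#' @inheritParams landuse_proportions
#' @return CONTAG in (0, 100].
#' @export
metric_contag <- function(grid, mask) {
  p <- landuse_proportions(grid, mask)
  present <- which(p > 0)
  if (length(present) == 1) return(100)
  g <- adjacency_counts(grid, mask)[present, present, drop = FALSE]
  if (sum(g) == 0) abort("no within-mask adjacencies; mask too small")
  p <- p[present]
  m <- length(present)
  pstar <- p * g / pmax(rowSums(g), .Machine$double.eps)
  terms <- pstar[pstar > 0]
  (1 + sum(terms * log(terms)) / (2 * log(m))) * 100
}

#' Human Activity Intensity of Land Surface (HAILS)
#'
#' Construction-land-equivalent share of the buffer, in percent: each class
#' area share is converted with a coefficient `CI_i` in `[0, 1]`
#' (construction land = 1) and summed, `HAILS = 100 * sum(p_i * CI_i)`.
#'
#' @param proportions Named class proportions (summing to 1).
#' @param ci Named coefficient vector; every class with nonzero proportion
#'   must be present.
#' @return HAILS in `[0, 100]`.
#' @export
hails <- function(proportions, ci) {
  used <- names(proportions)[proportions > 0]
  miss <- setdiff(used, names(ci))
  if (length(miss)) abort(paste("missing HAILS coefficient for class(es):",
                                paste(miss, collapse = ", ")))
  100 * sum(proportions[used] * ci[used])
}

#' Example HAILS construction-land-equivalent coefficients
#'
#' Placeholder table for testing and synthetic work, NOT an authoritative
#' transcription of any published coefficient set; supply your own via the
#' pipeline config for real analyses.
#' @return Named numeric vector over the seven classes.
#' @export
example_hails_ci <- function() {
  c(cultivated = 0.2, forest = 0.067, grass = 0.067, construction = 1,
    water = 0.067, wetland = 0.067, bare = 0)
}

#' Driver table: 11 landscape variables per site at one buffer radius
#'
#' For each site, the seven land-use class proportions plus LPI, CONTAG,
#' SHDI and HAILS inside the circular buffer.
#'
#' @param grid A `landuse_grid`.
#' @param sites Data frame with `site_id` and metric coordinates `x`, `y`.
#' @param radius Buffer radius (m).
#' @param ci HAILS coefficients (default the example placeholder table).
#' @return Tibble: `site_id`, `radius`, `prop_<class>` x7, `LPI`, `CONTAG`,
#'   `SHDI`, `HAILS`.
#' @export
driver_table <- function(grid, sites, radius, ci = example_hails_ci()) {
  sites <- tibble::as_tibble(sites)
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    mask <- extract_buffer(grid, sites[i, ], radius)
    p <- landuse_proportions(grid, mask)
    lab <- patch_label(grid, mask)
    out <- tibble::tibble(site_id = sites$site_id[i], radius = radius)
    for (nm in names(p)) out[[paste0("prop_", nm)]] <- unname(p[nm])
    out$LPI <- metric_lpi(lab)
    out$CONTAG <- metric_contag(grid, mask)
    out$SHDI <- metric_shdi(p)
    out$HAILS <- hails(p, ci)
    out
  })
}
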