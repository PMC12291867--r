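# Synthetic study generator. Emulates the survey layout the pipeline is
# designed for — ~50 sites in 3 regions sampled in 3 months, ~69 taxa, a
# 7-class land-use mosaic whose composition inside ONE true buffer radius
# drives water quality, and communities assembled under a tunable mix of
# environmental filtering (niche strength lambda) and dispersal limitation
# (decay length delta). Every generated quantity that downstream stages
# try to recover is returned as ground truth.

#' Specification for a synthetic study
#'
#' Defaults reproduce the survey structure the pipeline targets: 50 sites
#' split 16/14/20 over three regions, three months, 69 taxa, a 20 km x
#' 20 km landscape at 100 m resolution, candidate buffer radii 100-4000 m
#' with a true scale of 3000 m.
#'
#' @param n_sites Total sites (split over regions in proportions 16/14/20).
#' @param n_taxa Number of taxa.
#' @param grid_dim Grid edge length in cells.
#' @param cellsize Cell size (m).
#' @param class_props Proportions of the 7 land-use classes (sum to 1).
#' @param clumping Landscape smoothing length in cells (larger = larger
#'   patches); mean patch diameter is roughly `2 * clumping` cells.
#' @param radii Candidate buffer radii (m), strictly increasing.
#' @param r_star True buffer radius (m) through which land use drives
#'   water quality.
#' @param lambda Niche strength in `[0, 1]`: 1 = pure environmental
#'   filtering, 0 = pure dispersal assembly.
#' @param delta Dispersal decay length (m).
#' @param site_abundance Expected total individuals per site.
#' @param env_noise_sd Gaussian noise on the latent quality score, as a
#'   fraction of its spatial standard deviation.
#' @param months Month labels (independent environmental redraws sharing
#'   one landscape).
#' @param niche_breadth Niche width of each taxon on the latent quality
#'   axis, as a fraction of the score range.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_sites = 50, n_taxa = 69, grid_dim = 200,
                       cellsize = 100, class_props = c(cultivated = 0.30,
                         forest = 0.20, grass = 0.20, construction = 0.10,
                         water = 0.06, wetland = 0.04, bare = 0.10),
                       clumping = 4, radii = c(100, 500, 1000, 2000, 3000,
                                               4000),
                       r_star = 3000, lambda = 0.5, delta = 5000,
                       site_abundance = 500, env_noise_sd = 0.1,
                       months = c("April", "July", "October"),
                       niche_breadth = 0.25) {
  if (abs(sum(class_props) - 1) > 1e-8) abort("class proportions must sum to 1")
  if (lambda < 0 || lambda > 1) abort("lambda must lie in [0, 1]")
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0))
    abort("radii must be positive and strictly increasing")
  structure(as.list(environment()), class = "synth_spec")
}

# separable circular box blur, repeated; smooths iid noise into a field
# with correlation length ~ width cells
smooth_field <- function(m, width, passes = 3) {
  k <- rep(1 / (2 * width + 1), 2 * width + 1)
  for (i in seq_len(passes)) {
    m <- t(apply(m, 1, function(r) as.numeric(stats::filter(r, k,
                                                            circular = TRUE))))
    m <- apply(m, 2, function(cl) as.numeric(stats::filter(cl, k,
                                                           circular = TRUE)))
  }
  m
}

# land-cover classes ordered along the land-condition gradient, most
# degraded first: bare, construction, cultivated, grass, wetland, water,
# forest. The synthetic landscape and its water-quality response both
# follow this ordering.
DEGRADATION_ORDER <- c("bare", "construction", "cultivated", "grass",
                       "wetland", "water", "forest")

#' Generate a clumped categorical landscape
#'
#' A latent land-condition field (iid Gaussian noise passed through a
#' repeated box blur of width `clumping`) is quantile-binned into the
#' seven classes, arranged along a fixed degradation ordering (bare land
#' at the lowest condition values through construction, cultivated,
#' grass, wetland and water up to forest at the highest). Quantile
#' binning makes realized class proportions match the request to within
#' rounding, and the fixed ordering means spatially adjacent classes are
#' ecologically adjacent, as in real mosaics. Deterministic under
#' `set.seed()`.
#'
#' @param spec A [synth_spec()].
#' @return A `landuse_grid`.
#' @export
gen_landscape <- function(spec) {
  d <- spec$grid_dim
  if (d < 8 * spec$clumping)
    abort("grid too small for the requested clumping")
  props <- spec$class_props
  if (any(props == 1)) {                  # degenerate single-class case
    return(landuse_grid(matrix(as.integer(which(props == 1)), d, d),
                        cellsize = spec$cellsize))
  }
  field <- smooth_field(matrix(rnorm(d * d), d, d), spec$clumping)
  ord <- match(DEGRADATION_ORDER, names(landuse_classes()))
  cum <- cumsum(props[DEGRADATION_ORDER])
  qs <- quantile(field, cum[-length(cum)], type = 7)
  bin <- findInterval(field, qs, rightmost.closed = FALSE) + 1
  codes <- matrix(as.integer(ord[bin]), d, d)
  landuse_grid(codes, cellsize = spec$cellsize)
}

#' Place sampling sites on a synthetic landscape
#'
#' Sites fall uniformly at random at least `max(radii)` from every grid
#' edge (so all buffers are interior), split into three latitudinal
#' regions in the 16/14/20 layout proportions.
#'
#' @param spec A [synth_spec()].
#' @param grid The generated `landuse_grid`.
#' @return Site tibble: `site_id`, `x`, `y` (m), `longitude`, `latitude`
#'   (degrees, a local equirectangular mapping), `altitude` (m), `region`.
#' @export
gen_sites <- function(spec, grid) {
  margin <- max(spec$radii)
  extent <- spec$grid_dim * spec$cellsize
  if (extent - 2 * margin <= 0) abort("grid too small for the largest radius")
  n <- spec$n_sites
  reg_n <- round(n * c(YRIA = 16, CAZ = 14, SMA = 20) / 50)
  reg_n[3] <- n - sum(reg_n[1:2])
  region <- rep(names(reg_n), reg_n)
  # three latitudinal bands, north to south
  band <- match(region, names(reg_n))
  span <- (extent - 2 * margin) / 3
  y <- margin + (3 - band) * span + runif(n) * span
  x <- margin + runif(n) * (extent - 2 * margin)
  # local metric -> degrees anchored at 106 E, 37 N
  lat0 <- 37; lon0 <- 106
  lat <- lat0 + (y - extent / 2) / 111320
  lon <- lon0 + (x - extent / 2) / (111320 * cos(lat0 * pi / 180))
  alt <- 1000 + 0.5 * (extent - y) / 10 + rnorm(n, sd = 20)
  tibble::tibble(site_id = sprintf("S%02d", seq_len(n)), x = x, y = y,
                 longitude = lon, latitude = lat, altitude = alt,
                 region = region)
}

# deterministic water-quality response to buffer composition: the
# coefficients rise monotonically along the degradation ordering, so
# water quality is a smooth function of local land condition. Forest
# (strongest positive) and bare land (strongest negative) lead, as in
# surveys where those two classes dominate the explained spatial
# variance of water quality.
QUALITY_COEF <- c(cultivated = -0.5, forest = 1.5, grass = 0.1,
                  construction = -0.9, water = 0.5, wetland = 0.3,
                  bare = -1.5)

#' Generate water-quality variables from land use at the true scale
#'
#' Each site's latent quality score is a fixed linear function of its
#' land-use proportions inside the TRUE buffer radius `r_star`, plus
#' Gaussian noise (`env_noise_sd` x the spatial SD of the deterministic
#' score). The 13 physicochemical indicators are monotone functions of the
#' score plus their own proportional noise, spanning the example WQI curve
#' domains. Ground truth (coefficients, per-site deterministic scores,
#' `r_star`) is attached as attributes.
#'
#' @param spec A [synth_spec()].
#' @param grid The landscape.
#' @param sites Site table from [gen_sites()].
#' @param month Optional month label added to the output.
#' @return Environmental tibble (site_id, 13 indicators) with attributes
#'   `quality` (latent score in 0..1) and `ground_truth`.
#' @export
gen_env <- function(spec, grid, sites, month = NULL) {
  comp <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    mask <- extract_buffer(grid, sites[i, ], spec$r_star)
    as.list(landuse_proportions(grid, mask))
  })
  score_det <- drop(as.matrix(comp) %*% QUALITY_COEF[colnames(comp)])
  s_sd <- max(sd(score_det), 1e-8)
  score <- score_det + rnorm(nrow(sites), sd = spec$env_noise_sd * s_sd)
  # map to (0, 1), 1 = pristine; the deterministic score is standardized
  # first so sites span most of the axis regardless of landscape contrast
  qual <- stats::plogis(1.5 * (score - mean(score_det)) / s_sd)
  # the 13 indicators are deterministic monotone maps of the (noisy)
  # latent score — the single Gaussian noise term lives on the score
  interp <- function(bad, good) bad + qual * (good - bad)
  env <- tibble::tibble(
    site_id = sites$site_id,
    pH = 7.25 + (1 - qual) * 1.2,
    WT = 16 + (1 - qual) * 6,
    EC = interp(1600, 200),
    TUR = interp(90, 4),
    DO = interp(3.5, 10.5),
    TDS = interp(1200, 120),
    TN = interp(6.5, 0.4),
    NH3N = interp(2.4, 0.05),
    NO2N = interp(0.45, 0.005),
    NO3N = interp(9, 0.3),
    TP = interp(0.9, 0.02),
    CODMn = interp(14, 1.5),
    Chla = interp(45, 2))
  if (!is.null(month)) env$month <- month
  attr(env, "quality") <- qual
  attr(env, "ground_truth") <- list(r_star = spec$r_star,
                                    coefficients = QUALITY_COEF,
                                    score_det = drop(score_det))
  env
}

#' Assemble a metacommunity under mixed niche and dispersal control
#'
#' Expected relative abundance of taxon k at site s is
#' `niche(s,k)^lambda * dispersal(s,k)^(1-lambda)`, with a Gaussian niche
#' kernel on the latent quality axis (optimum `mu_k`, breadth `sigma_k`)
#' and exponential dispersal decay from the taxon's home site (`h_k`,
#' length `delta`). Rows are normalized and counts drawn Poisson with the
#' site's expected total. Ground truth (`mu`, `sigma`, home sites,
#' `lambda`, `delta`) is attached.
#'
#' @param spec A [synth_spec()].
#' @param env Output of [gen_env()] (supplies the latent quality axis).
#' @param sites Site table.
#' @return A `community_matrix` with attribute `ground_truth`.
#' @export
gen_community <- function(spec, env, sites) {
  qual <- attr(env, "quality")
  if (is.null(qual)) abort("env must come from gen_env() (quality attribute)")
  n <- nrow(sites); K <- spec$n_taxa
  lam <- spec$lambda
  if (lam < 0 || lam > 1) abort("lambda must lie in [0, 1]")
  mu <- runif(K)                       # niche optima on the quality axis
  sig <- rep(spec$niche_breadth, K)
  home <- sample.int(n, K, replace = TRUE)
  dxy <- as.matrix(dist(sites[, c("x", "y")]))
  niche <- exp(-(outer(qual, mu, "-")^2) / (2 * matrix(sig^2, n, K,
                                                       byrow = TRUE)))
  disp <- exp(-dxy[, home] / spec$delta)          # n x K
  w <- niche^lam * disp^(1 - lam)
  w <- w / pmax(rowSums(w), .Machine$double.eps)
  counts <- matrix(rpois(n * K, lambda = w * spec$site_abundance), n, K)
  # ensure no empty site (resample minimal fix: give the modal taxon 1)
  empty <- rowSums(counts) == 0
  if (any(empty)) counts[cbind(which(empty), max.col(w[empty, , drop = FALSE]))] <- 1
  df <- data.frame(site_id = sites$site_id, counts)
  names(df)[-1] <- sprintf("taxon%02d", seq_len(K))
  cm <- community_matrix(df)
  attr(cm, "ground_truth") <- list(mu = mu, sigma = sig, home = home,
                                   lambda = lam, delta = spec$delta)
  cm
}

#' Generate a complete synthetic study
#'
#' Landscape, sites, and per-month environment + community bundles, all
#' reproducible from one seed.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return List of class `synth_study`: `spec`, `grid`, `sites`,
#'   `env` (tibble over months), `communities` (named list of
#'   `community_matrix` per month), `ground_truth`.
#' @export
gen_study <- function(spec = synth_spec(), seed = 1) {
  set.seed(seed)
  grid <- gen_landscape(spec)
  sites <- gen_sites(spec, grid)
  envs <- list(); comms <- list()
  for (m in spec$months) {
    e <- gen_env(spec, grid, sites, month = m)
    envs[[m]] <- e
    comms[[m]] <- gen_community(spec, e, sites)
  }
  structure(list(spec = spec, grid = grid, sites = sites,
                 env = dplyr::bind_rows(envs), communities = comms,
                 env_by_month = envs,
                 ground_truth = list(r_star = spec$r_star,
                                     lambda = spec$lambda,
                                     delta = spec$delta,
                                     quality_coef = QUALITY_COEF)),
            class = "synth_study")
}

#' Write a synthetic study to a plain-text fixture bundle
#'
#' CSVs (community per month, sites, environment), the landscape as ESRI
#' ASCII, and a ground-truth JSON.
#'
#' @param study A [gen_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$sites, file.path(dir, "sites.csv"))
  readr::write_csv(study$env, file.path(dir, "env.csv"))
  for (m in names(study$communities)) {
    cm <- study$communities[[m]]
    df <- data.frame(site_id = rownames(cm), unclass(cm),
                     check.names = FALSE)
    readr::write_csv(df, file.path(dir, paste0("community_", m, ".csv")))
  }
  write_landuse_asc(study$grid, file.path(dir, "landuse.asc"))
  jsonlite::write_json(study$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
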