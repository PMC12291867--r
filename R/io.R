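# File-based entry points: CSV community/site/environment tables, ESRI
# ASCII land use, YAML pipeline configuration. All site ids are
# cross-referenced and every returned object is ordered identically.

#' Read a community CSV
#'
#' Comma-separated, UTF-8, mandatory header; the first column holds site
#' ids, the remaining columns integer counts per taxon.
#'
#' @param path CSV path.
#' @param ... Passed to [community_matrix()].
#' @return A `community_matrix`.
#' @export
read_community <- function(path, ...) {
  community_matrix(readr::read_csv(path, show_col_types = FALSE), ...)
}

#' Read a site table CSV
#' @param path CSV path (columns `site_id`, `longitude`, `latitude`,
#'   `altitude`, optionally `region`, `month`, `x`, `y`).
#' @return Validated tibble.
#' @export
read_sites <- function(path) {
  validate_sites(readr::read_csv(path, show_col_types = FALSE))
}

#' Read an environmental table CSV
#' @param path CSV path (`site_id` plus numeric variables).
#' @param impute See [validate_env()].
#' @return Validated tibble.
#' @export
read_env <- function(path, impute = "none") {
  validate_env(readr::read_csv(path, show_col_types = FALSE), impute = impute)
}

#' Pipeline configuration
#'
#' Bundles the analysis settings: buffer radii, OPGD search space, WQI
#' parameter specs, HAILS coefficients, null-model and GDM settings.
#' [default_config()] carries the package's example (placeholder) WQI and
#' HAILS tables; [read_config()] loads and merges a YAML file over it.
#'
#' @param radii Buffer radii in metres, strictly increasing.
#' @param opgd_methods,opgd_k_range OPGD discretization search space.
#' @param wqi_params List of [wqi_param()] objects.
#' @param wqi_thresholds Classification bands, see [classify_wqi()].
#' @param hails_ci Named HAILS coefficients.
#' @param null_draws,null_seed Null-model randomizations and seed.
#' @param gdm_splines,gdm_knots GDM basis settings.
#' @return List of class `pipeline_config`.
#' @export
default_config <- function(radii = c(100, 500, 1000, 2000, 3000, 4000),
                           opgd_methods = c("equal", "quantile", "natural",
                                            "geometric", "sd"),
                           opgd_k_range = 3:7,
                           wqi_params = example_wqi_params(),
                           wqi_thresholds = wqi_classes(),
                           hails_ci = example_hails_ci(),
                           null_draws = 1000, null_seed = 42,
                           gdm_splines = 3, gdm_knots = NULL) {
  if (is.unsorted(radii, strictly = TRUE) || any(radii <= 0))
    abort("radii must be positive and strictly increasing")
  structure(list(radii = radii, opgd_methods = opgd_methods,
                 opgd_k_range = opgd_k_range, wqi_params = wqi_params,
                 wqi_thresholds = wqi_thresholds, hails_ci = hails_ci,
                 null_draws = null_draws, null_seed = null_seed,
                 gdm_splines = gdm_splines, gdm_knots = gdm_knots),
            class = "pipeline_config")
}

#' @rdname default_config
#' @param path YAML file; recognised top-level keys: `radii`,
#'   `opgd: {methods, k_min, k_max}`, `wqi: {params: [{name, weight,
#'   curve: {value: [...], score: [...]}}], thresholds: [{lower, upper,
#'   label}]}`, `hails_ci` (name: coefficient), `null_model: {draws,
#'   seed}`, `gdm: {splines}`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(y$radii)) cfg$radii <- sort(as.numeric(y$radii))
  if (!is.null(y$opgd$methods)) cfg$opgd_methods <- y$opgd$methods
  if (!is.null(y$opgd$k_min))
    cfg$opgd_k_range <- seq(y$opgd$k_min, y$opgd$k_max)
  if (!is.null(y$wqi$params)) {
    cfg$wqi_params <- lapply(y$wqi$params, function(p)
      wqi_param(p$name, p$weight,
                data.frame(value = as.numeric(p$curve$value),
                           score = as.numeric(p$curve$score))))
    names(cfg$wqi_params) <- vapply(cfg$wqi_params, function(s) s$name,
                                    character(1))
  }
  if (!is.null(y$wqi$thresholds))
    cfg$wqi_thresholds <- do.call(rbind, lapply(y$wqi$thresholds,
                                                as.data.frame))
  if (!is.null(y$hails_ci)) cfg$hails_ci <- unlist(y$hails_ci)
  if (!is.null(y$null_model$draws)) cfg$null_draws <- y$null_model$draws
  if (!is.null(y$null_model$seed)) cfg$null_seed <- y$null_model$seed
  if (!is.null(y$gdm$splines)) cfg$gdm_splines <- y$gdm$splines
  cfg
}

#' Load a complete dataset bundle
#'
#' Reads community, site, environmental and land-use files, cross-checks
#' site ids, and orders every object identically (site-table order).
#'
#' @param community_path,sites_path,env_path CSV paths.
#' @param grid_path ESRI ASCII land-use path.
#' @param config_path Optional YAML config (default settings otherwise).
#' @return List: `community`, `sites`, `env`, `grid`, `config`.
#' @export
load_dataset <- function(community_path, sites_path, env_path, grid_path,
                         config_path = NULL) {
  for (p in c(community_path, sites_path, env_path, grid_path))
    if (!file.exists(p)) abort(paste("file not found:", p))
  sites <- read_sites(sites_path)
  cm <- read_community(community_path)
  env <- read_env(env_path)
  check_same_sites(rownames(cm), sites$site_id, "community and site table")
  check_same_sites(unique(env$site_id), sites$site_id,
                   "environment and site table")
  ord <- sites$site_id
  cm2 <- unclass(cm)[ord, , drop = FALSE]
  cm <- structure(cm2, class = class(cm),
                  allow_empty_sites = attr(cm, "allow_empty_sites"))
  env <- env[order(match(env$site_id, ord)), ]
  grid <- read_landuse_asc(grid_path)
  config <- if (is.null(config_path)) default_config()
            else read_config(config_path)
  list(community = cm, sites = sites, env = env, grid = grid,
       config = config)
}
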