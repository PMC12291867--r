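# Small in-code fixtures shared across test files.

random_community <- function(n_sites = 6, n_taxa = 10, seed = NULL,
                             prob_zero = 0.3, max_count = 20) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_sites * n_taxa, 5) *
                (runif(n_sites * n_taxa) > prob_zero),
              n_sites, n_taxa)
  # guarantee non-empty sites
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_taxa, sum(empty), replace = TRUE))] <- 1
  df <- data.frame(site_id = sprintf("s%02d", seq_len(n_sites)), m)
  community_matrix(df)
}

tiny_grid <- function(codes, cellsize = 10) {
  landuse_grid(codes, cellsize = cellsize, xll = 0, yll = 0)
}

uniform_grid <- function(n = 11, class = 1L, cellsize = 10) {
  tiny_grid(matrix(class, n, n), cellsize)
}

# site table in the 16/14/20 regional layout
layout_sites <- function() {
  n <- c(YRIA = 16, CAZ = 14, SMA = 20)
  set.seed(99)
  tibble::tibble(site_id = sprintf("S%02d", 1:50),
                 longitude = runif(50, 104.3, 107.6),
                 latitude = runif(50, 35.2, 39.4),
                 altitude = runif(50, 1000, 2400),
                 region = rep(names(n), n))
}
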