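#' Harmonic number helpers used by Watterson's theta and Tajima's D
#'
#' @param n integer, number of sequences.
#' @return `a1(n)` is \eqn{\sum_{i=1}^{n-1} 1/i}; `a2(n)` the corresponding
#'   sum of inverse squares.
#' @keywords internal
a1 <- function(n) sum(1 / seq_len(n - 1L))

#' @rdname a1
#' @keywords internal
a2 <- function(n) sum(1 / seq_len(n - 1L)^2)

#' Derive a per-stage random seed from a master seed
#'
#' Expands one user-facing seed into independent sub-seeds so that toggling
#' one analysis stage does not shift the random draws of another. Uses a
#' simple multiplicative hash on the stage name, kept below 2^31.
#'
#' @param seed master integer seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Great-circle distance between coordinate pairs
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree WGS84 coordinates (vectorized).
#' @return distance in kilometers.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

#' Pairwise great-circle distance matrix for a set of sites
#'
#' @param coords data frame with columns `lat`, `lon` (and optionally
#'   rownames / a `site_id` column used for dimnames).
#' @return symmetric matrix of distances in km.
#' @export
site_distance_matrix <- function(coords) {
  n <- nrow(coords)
  ids <- if (!is.null(coords$site_id)) coords$site_id else rownames(coords)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d[i, ] <- haversine_km(coords$lat[i], coords$lon[i], coords$lat, coords$lon)
  }
  (d + t(d)) / 2
}

# permutation p-value with the observed configuration counted once
perm_pvalue <- function(n_as_extreme, n_perm) (n_as_extreme + 1) / (n_perm + 1)

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
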