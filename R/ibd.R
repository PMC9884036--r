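#' Edwards' chord distance between groups
#'
#' Cavalli-Sforza & Edwards chord distance computed from per-group allele
#' frequencies, averaged over loci:
#' D = sqrt(1 - (1/L) sum_l sum_a sqrt(p1 p2)).
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition` (typically collection sites).
#' @return symmetric distance matrix over groups.
#' @export
chord_distance <- function(gm, part) {
  part <- part_align(part, gm$samples)
  gs <- levels(part)
  K <- length(gs)
  L <- length(gm$loci)
  # per-locus frequency tables
  freqs <- lapply(seq_len(L), function(l) {
    lapply(gs, function(g) {
      cnt <- allele_counts(gm, l, which(part == g))
      if (sum(cnt) == 0) return(NULL)
      stats::setNames(as.numeric(cnt) / sum(cnt), names(cnt))
    })
  })
  d <- matrix(0, K, K, dimnames = list(gs, gs))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    acc <- 0; used <- 0
    for (l in seq_len(L)) {
      pa <- freqs[[l]][[a]]; pb <- freqs[[l]][[b]]
      if (is.null(pa) || is.null(pb)) next
      alle <- union(names(pa), names(pb))
      s <- sum(sqrt(ifelse(alle %in% names(pa), pa[alle], 0) *
                    ifelse(alle %in% names(pb), pb[alle], 0)))
      acc <- acc + s
      used <- used + 1
    }
    d[a, b] <- d[b, a] <- sqrt(max(0, 1 - acc / used))
  }
  d
}

#' Mantel test between genetic and geographic distance matrices
#'
#' Monte-Carlo Mantel test (one-sided, r >= observed) via [vegan::mantel()].
#'
#' @param dist_gen,dist_geo square symmetric matrices of equal order >= 3.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return list of class `ibd_result`: `mantel_r`, `mantel_p`, `n_perm`.
#' @export
mantel_test <- function(dist_gen, dist_geo, n_perm = 999, seed = 1L) {
  stopifnot(nrow(dist_gen) == nrow(dist_geo), nrow(dist_gen) >= 3)
  if (stats::sd(dist_gen[lower.tri(dist_gen)]) == 0 ||
      stats::sd(dist_geo[lower.tri(dist_geo)]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  fit <- with_seed(stage_seed(seed, "mantel"),
    vegan::mantel(stats::as.dist(dist_gen), stats::as.dist(dist_geo),
                  permutations = n_perm))
  structure(list(mantel_r = unname(fit$statistic),
                 mantel_p = unname(fit$signif), n_perm = n_perm),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  if (!is.null(x$mantel_r))
    cat(sprintf("Mantel r = %.3f, p = %.4g (%d permutations)\n",
                x$mantel_r, x$mantel_p, x$n_perm))
  if (!is.null(x$slope))
    cat(sprintf("IBD slope b = %.4f (95%% CI %.4f-%.4f)\n",
                x$slope, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearized genetic distance Fst/(1-Fst) on
#' log-transformed geographic distance (km). When the genotype data are
#' supplied, a 95% CI for the slope is obtained by bootstrap over loci
#' (pairwise Fst recomputed per resample).
#'
#' @param fst_matrix an `fst_matrix` or plain symmetric Fst matrix.
#' @param geo_km symmetric geographic distance matrix (km), same group
#'   order.
#' @param gm,part optional genotype matrix + partition for the locus
#'   bootstrap CI.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return `ibd_result` with `slope`, `intercept`, `ci` (when available),
#'   `n_pairs`.
#' @export
ibd_regression <- function(fst_matrix, geo_km, gm = NULL, part = NULL,
                           n_boot = 1000, seed = 1L) {
  f <- if (inherits(fst_matrix, "fst_matrix")) fst_matrix$values else fst_matrix
  lt <- lower.tri(f)
  fst <- f[lt]; km <- geo_km[lt]
  drop <- !is.na(fst) & fst >= 1
  if (any(drop)) warning("excluding ", sum(drop), " pair(s) with Fst = 1")
  use <- !is.na(fst) & fst < 1 & km > 0
  y <- fst[use] / (1 - fst[use])
  x <- log(km[use])
  fit <- stats::lm(y ~ x)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              ci = NULL, n_pairs = sum(use))
  if (!is.null(gm)) {
    part <- part_align(part, gm$samples)
    gs <- levels(part)
    slopes <- with_seed(stage_seed(seed, "ibdboot"),
                        vapply(seq_len(n_boot), function(r) {
      li <- sample(length(gm$loci), replace = TRUE)
      sub <- gm_subset(gm, loci = li)
      fb <- matrix(NA_real_, length(gs), length(gs))
      for (a in seq_len(length(gs) - 1)) for (b in (a + 1):length(gs))
        fb[b, a] <- wc_pair_theta(sub, part, gs[a], gs[b])
      fbl <- fb[lower.tri(fb)]
      ub <- !is.na(fbl) & fbl < 1 & km > 0
      stats::coef(stats::lm(fbl[ub] / (1 - fbl[ub]) ~ log(km[ub])))[2]
    }, 0))
    out$ci <- unname(stats::quantile(slopes, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(out, class = "ibd_result")
}

#' Site-level isolation-by-distance Mantel test
#'
#' Groups samples by collection site (minimum size configurable, default
#' 2), computes Edwards' chord genetic distances and great-circle
#' geographic distances between site centroids, and runs the Mantel test.
#'
#' @param gm a `genotype_matrix`.
#' @param meta `sample_metadata` with site_id, lat, lon.
#' @param min_per_site minimum samples per retained site (default 2).
#' @param n_perm Mantel permutations (default 999).
#' @param seed integer seed.
#' @return `ibd_result` plus `n_sites` and the dropped sites.
#' @export
site_ibd_mantel <- function(gm, meta, min_per_site = 2, n_perm = 999,
                            seed = 1L) {
  meta <- meta[match(gm$samples, meta$sample_id), ]
  tab <- table(meta$site_id)
  keep_sites <- names(tab)[tab >= min_per_site]
  sel <- which(meta$site_id %in% keep_sites)
  if (length(keep_sites) < 3) stop("fewer than 3 sites after filtering")
  sub <- gm_subset(gm, sel)
  spart <- pop_partition(stats::setNames(as.character(meta$site_id[sel]),
                                         sub$samples))
  gd <- chord_distance(sub, spart)
  cent <- do.call(rbind, lapply(levels(spart), function(s) {
    i <- sel[meta$site_id[sel] == s]
    data.frame(site_id = s, lat = mean(meta$lat[i]), lon = mean(meta$lon[i]))
  }))
  geo <- site_distance_matrix(cent)
  res <- mantel_test(gd, geo[levels(spart), levels(spart)], n_perm, seed)
  res$n_sites <- length(keep_sites)
  res$dropped_sites <- setdiff(names(tab), keep_sites)
  res
}
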