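# per-allele dosage coding of the whole genotype matrix (columns named
# locus.allele), missing imputed by column mean, used for ordination only
dosage_table <- function(gm, impute = TRUE) {
  cols <- list()
  for (l in seq_along(gm$loci)) {
    D <- dosage_matrix(gm, l)
    colnames(D) <- paste(gm$loci[l], colnames(D), sep = ".")
    cols[[l]] <- D
  }
  X <- do.call(cbind, cols)
  if (impute) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  }
  X
}

#' Principal components analysis of genotypes
#'
#' Samples are coded as 0/1/2 per-allele dosage columns, column-centered,
#' with missing calls imputed by the column mean (imputation is for
#' ordination only, never for estimators). Decomposition by SVD.
#'
#' @param gm a `genotype_matrix`.
#' @param n_axes axes to return (default 10, capped at rank).
#' @return list of class `ordination`: `scores` (samples x axes),
#'   `percent_variance` per axis, `method = "pca"`.
#' @export
run_pca <- function(gm, n_axes = 10) {
  X <- dosage_table(gm)
  X <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(X)
  pos <- sv$d > 1e-10
  lam <- sv$d[pos]^2
  k <- min(n_axes, sum(pos))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)],
                                                      k, k)
  rownames(scores) <- gm$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 percent_variance = 100 * lam[seq_len(k)] / sum(lam),
                 method = "pca"),
            class = "ordination")
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant analysis on the leading principal-component scores
#' of the dosage-coded genotypes: axes maximizing between-group relative to
#' within-group variance.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition` with >= 2 groups.
#' @param n_pcs retained PCs; default: smallest number explaining >= 80%
#'   of total variance.
#' @return list of class `ordination`: `scores` (discriminant scores),
#'   `percent_variance` (percent of discriminant trace), `n_pcs`,
#'   `group` the partition used, `method = "dapc"`.
#' @export
run_dapc <- function(gm, part, n_pcs = NULL) {
  part <- part_align(part, gm$samples)
  if (nlevels(part) < 2) stop("DAPC needs >= 2 groups")
  pca <- run_pca(gm, n_axes = length(gm$samples))
  cum <- cumsum(pca$percent_variance)
  if (is.null(n_pcs)) n_pcs <- which(cum >= 80)[1]
  if (n_pcs >= ncol(pca$scores) + 1) stop("n_pcs exceeds available rank")
  Z <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(Z, grouping = part)
  sc <- stats::predict(fit, Z)$x
  rownames(sc) <- gm$samples
  structure(list(scores = sc,
                 percent_variance = 100 * fit$svd^2 / sum(fit$svd^2),
                 n_pcs = n_pcs, group = part, method = "dapc"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s: %d samples, %d axes (axis 1: %.2f%% variance)\n",
              toupper(x$method), nrow(x$scores), ncol(x$scores),
              x$percent_variance[1]))
  invisible(x)
}
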