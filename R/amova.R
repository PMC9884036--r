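#' Pairwise sequence-difference matrix
#'
#' Number of nucleotide differences between every pair of sequences,
#' counted over sites where both members carry unambiguous bases.
#'
#' @param aln a `dna_alignment`.
#' @return symmetric numeric matrix.
#' @export
pairwise_diff_matrix <- function(aln) {
  m <- aln_matrix(aln)
  ok <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$samples, aln$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use])
  }
  d
}

# two-level PhiST from a squared-distance matrix and a 2+-level factor
phist_from_dist <- function(d2, grp) {
  grp <- droplevels(as.factor(grp))
  N <- nrow(d2)
  K <- nlevels(grp)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- 0
  ng <- as.numeric(table(grp))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1)
      ssd_within <- ssd_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- K - 1
  df_within <- N - K
  ms_within <- ssd_within / df_within
  ms_among <- ssd_among / df_among
  n_eff <- (N - sum(ng^2) / N) / (K - 1)
  s2w <- ms_within
  s2a <- (ms_among - ms_within) / n_eff
  s2a / (s2a + s2w)
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical partition of molecular variance from squared
#' inter-individual distances (Excoffier, Smouse & Quattro 1992).
#' For sequence data (`dna_alignment`) the two-level design is used
#' (among groups / within groups) with distances = pairwise difference
#' counts. For diploid microsatellites (`genotype_matrix`) the three-level
#' design over gene copies is used (among groups / among individuals within
#' groups / within individuals); the gene-copy distance is summed over loci
#' as allele non-identity (0/1 per locus) or squared size difference
#' (`distance = "size"`, an R_ST-style alternative).
#'
#' Variance components are reported as estimated (possibly negative);
#' percentages are computed both from raw components and after truncating
#' negatives at zero.
#'
#' @param data `dna_alignment` or `genotype_matrix`.
#' @param part a `pop_partition` with >= 2 groups.
#' @param n_perm permutations for significance (default 999).
#' @param distance microsatellite gene-copy distance: `"identity"` or
#'   `"size"`.
#' @param seed integer seed.
#' @return list of class `amova_result`: `components` data frame (source,
#'   df, SSD, variance, percent, percent_truncated), `phi` fixation
#'   indices, `p_values`.
#' @export
amova <- function(data, part, n_perm = 999, distance = c("identity", "size"),
                  seed = 1L) {
  distance <- match.arg(distance)
  if (inherits(data, "dna_alignment")) {
    part <- part_align(part, data$samples)
    d2 <- pairwise_diff_matrix(data)
    res <- amova2_fit(d2, part)
    phi_perm <- with_seed(stage_seed(seed, "amova_mt"),
      vapply(seq_len(n_perm), function(r)
        phist_from_dist(d2, sample(part)), 0))
    p_st <- perm_pvalue(sum(phi_perm >= res$phi["Phi_ST"] - 1e-12), n_perm)
    res$p_values <- c(Phi_ST = p_st)
    return(res)
  }
  gm <- data
  part <- part_align(part, gm$samples)
  d2 <- copy_distance_matrix(gm, distance)
  fit <- amova3_fit(d2, part)
  phi_perm <- with_seed(stage_seed(seed, "amova_msat"),
    vapply(seq_len(n_perm), function(r)
      amova3_fit(d2, sample(part), components_only = TRUE)["Phi_ST"], 0))
  fit$p_values <- c(Phi_ST = perm_pvalue(
    sum(phi_perm >= fit$phi["Phi_ST"] - 1e-12), n_perm))
  fit
}

# squared distance between gene copies summed over loci; copies 2i-1, 2i
# belong to individual i; loci with a missing call in either individual
# contribute 0 between those copies (complete information accumulates)
copy_distance_matrix <- function(gm, distance = "identity") {
  N <- length(gm$samples)
  d2 <- matrix(0, 2 * N, 2 * N)
  for (l in seq_along(gm$loci)) {
    a <- as.vector(rbind(gm$calls[, l, 1], gm$calls[, l, 2]))
    typed <- which(!is.na(a))
    if (distance == "identity") {
      dd <- outer(a[typed], a[typed], function(x, y) as.numeric(x != y))
    } else {
      u <- a[typed] / gm$motif_length[l]
      dd <- outer(u, u, function(x, y) (x - y)^2)
    }
    d2[typed, typed] <- d2[typed, typed] + dd
  }
  d2
}

# two-level AMOVA fit from squared distances
amova2_fit <- function(d2, grp) {
  grp <- droplevels(as.factor(grp))
  N <- nrow(d2); K <- nlevels(grp)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_within <- 0
  ng <- as.numeric(table(grp))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1)
      ssd_within <- ssd_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  df <- c(K - 1, N - K)
  ms <- c(ssd_among, ssd_within) / df
  n_eff <- (N - sum(ng^2) / N) / (K - 1)
  s2w <- ms[2]
  s2a <- (ms[1] - ms[2]) / n_eff
  v <- c(s2a, s2w)
  vt <- pmax(v, 0)
  comp <- data.frame(
    source = c("among groups", "within groups"),
    df = df, SSD = c(ssd_among, ssd_within),
    variance = v,
    percent = 100 * v / sum(v),
    percent_truncated = 100 * vt / sum(vt))
  structure(list(components = comp,
                 phi = c(Phi_ST = s2a / (s2a + s2w)),
                 p_values = NULL),
            class = "amova_result")
}

# three-level diploid AMOVA over gene copies from a precomputed copy
# distance matrix (see copy_distance_matrix)
amova3_fit <- function(d2, grp, components_only = FALSE) {
  grp <- droplevels(as.factor(grp))
  N <- nrow(d2) / 2
  K <- nlevels(grp)
  ind_of_copy <- rep(seq_len(N), each = 2)
  grp_of_copy <- grp[ind_of_copy]
  Nc <- 2 * N
  ssd_total <- sum(d2[upper.tri(d2)]) / Nc
  # within individuals
  ssd_wi <- sum(vapply(seq_len(N), function(i)
    d2[2 * i - 1, 2 * i] / 2, 0))
  # within groups (copies)
  ssd_wg <- 0
  ng <- as.numeric(table(grp)) # individuals per group
  for (g in levels(grp)) {
    idx <- which(grp_of_copy == g)
    ssd_wg <- ssd_wg + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ssd_ai <- ssd_wg - ssd_wi           # among individuals within groups
  ssd_ag <- ssd_total - ssd_wg        # among groups
  df <- c(K - 1, N - K, N)
  ms <- c(ssd_ag, ssd_ai, ssd_wi) / df
  s2c <- ms[3]
  s2b <- (ms[2] - s2c) / 2
  ncopies_g <- 2 * ng
  n_eff <- (Nc - sum(ncopies_g^2) / Nc) / (K - 1)
  s2a <- (ms[1] - s2c - 2 * s2b) / n_eff
  v <- c(s2a, s2b, s2c)
  tot <- sum(v)
  phi <- c(Phi_ST = s2a / tot,
           Phi_IS = s2b / (s2b + s2c),
           Phi_IT = (s2a + s2b) / tot)
  if (components_only) return(phi)
  vt <- pmax(v, 0)
  comp <- data.frame(
    source = c("among groups", "among individuals within groups",
               "within individuals"),
    df = df, SSD = c(ssd_ag, ssd_ai, ssd_wi),
    variance = v,
    percent = 100 * v / tot,
    percent_truncated = 100 * vt / sum(vt))
  structure(list(components = comp, phi = phi, p_values = NULL),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  print(transform(x$components,
                  SSD = round(SSD, 3), variance = round(variance, 4),
                  percent = round(percent, 2),
                  percent_truncated = round(percent_truncated, 2)))
  cat("Phi: ", paste(names(x$phi), round(x$phi, 4), sep = "=",
                     collapse = "  "), "\n")
  if (!is.null(x$p_values))
    cat("p:   ", paste(names(x$p_values), signif(x$p_values, 3), sep = "=",
                       collapse = "  "), "\n")
  invisible(x)
}
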