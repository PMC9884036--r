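#' Linkage-disequilibrium effective population size
#'
#' Single-sample contemporary Ne from the Burrows composite disequilibrium
#' correlation between unlinked microsatellite loci (Waples 2006; Waples &
#' Do 2008), assuming random mating. For each locus pair and each pair of
#' alleles passing the frequency screen, the composite Burrows correlation
#' is computed from allele dosages with the n/(n-1) correction; r-squared
#' values are averaged within locus pairs and combined across pairs with
#' sample-size weights. The expected no-drift sampling component of this
#' r-squared construction, E = 1/(S-1) + 1.1/S^2 with S the weighted
#' harmonic-mean sample size (calibrated on null simulations of unlinked
#' loci at Hardy-Weinberg proportions, the same route by which the
#' published coefficient sets were derived for their own r-squared), is
#' subtracted, and Ne is obtained from the random-mating quadratic
#' Ne = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2'); r2' <= 0 reports
#' infinity (no drift signal).
#'
#' Confidence intervals: jackknife over locus pairs, and parametric
#' (chi-square with effective degrees of freedom = total number of allele
#' comparisons).
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`; estimate computed within `group`.
#' @param group group label (default first group).
#' @param maf alleles with frequency below this are excluded (default
#'   0.05).
#' @return list of class `ne_estimate`: `ne`, `r2`, `r2_drift`,
#'   `expected_r2`, `ci_jackknife`, `ci_parametric`, `S` harmonic-mean
#'   sample size, `n_pairs`, `n_comparisons`.
#' @export
ld_ne_estimate <- function(gm, part, group = NULL, maf = 0.05) {
  part <- part_align(part, gm$samples)
  if (is.null(group)) group <- levels(part)[1]
  idx <- which(part == group)
  if (length(idx) < 10) stop("need n >= 10 individuals")
  L <- length(gm$loci)
  # dosage matrices with MAF screen
  dos <- vector("list", L)
  for (l in seq_len(L)) {
    D <- dosage_matrix(gm, l, idx)
    typed <- !is.na(D[, 1])
    p <- colSums(D[typed, , drop = FALSE]) / (2 * sum(typed))
    keep <- p >= maf & p <= 1 - maf
    if (sum(keep) >= 2) dos[[l]] <- D[, keep, drop = FALSE]
  }
  use <- which(!vapply(dos, is.null, TRUE))
  if (length(use) < 2) stop("no locus pairs survive the frequency screen")
  pair_r2 <- pair_n <- pair_k <- numeric(0)
  for (ii in seq_along(use)[-length(use)]) {
    for (jj in (ii + 1):length(use)) {
      D1 <- dos[[use[ii]]]; D2 <- dos[[use[jj]]]
      both <- !is.na(D1[, 1]) & !is.na(D2[, 1])
      n <- sum(both)
      if (n < 10) next
      r2s <- c()
      for (a in seq_len(ncol(D1))) for (b in seq_len(ncol(D2))) {
        x <- D1[both, a]; y <- D2[both, b]
        px <- mean(x) / 2; py <- mean(y) / 2
        if (px <= 0 || px >= 1 || py <= 0 || py >= 1) next
        delta <- stats::cov(x, y) / 2 # includes the n/(n-1) correction
        r <- delta / sqrt(px * (1 - px) * py * (1 - py))
        r2s <- c(r2s, r^2)
      }
      if (!length(r2s)) next
      pair_r2 <- c(pair_r2, mean(r2s))
      pair_n <- c(pair_n, n)
      pair_k <- c(pair_k, length(r2s))
    }
  }
  if (!length(pair_r2)) stop("no usable locus pairs")
  w <- pair_n
  r2_mean <- sum(w * pair_r2) / sum(w)
  S <- sum(w) / sum(w / pair_n) # weighted harmonic mean of pair sample sizes
  ne_from_r2 <- function(r2, S) {
    exp_r2 <- 1 / (S - 1) + 1.1 / S^2
    r2d <- r2 - exp_r2
    if (r2d <= 0) return(Inf)
    disc <- 1 / 9 - 2.76 * r2d
    if (disc < 0) disc <- 0
    (1 / 3 + sqrt(disc)) / (2 * r2d)
  }
  ne <- ne_from_r2(r2_mean, S)
  # jackknife over locus pairs
  ci_j <- c(NA_real_, NA_real_)
  if (length(pair_r2) > 1) {
    jk <- vapply(seq_along(pair_r2), function(d) {
      sum(w[-d] * pair_r2[-d]) / sum(w[-d])
    }, 0)
    m <- length(jk)
    jbar <- mean(jk)
    var_j <- (m - 1) / m * sum((jk - jbar)^2)
    se <- sqrt(var_j)
    r2_lo <- r2_mean - 1.96 * se
    r2_hi <- r2_mean + 1.96 * se
    ci_j <- c(ne_from_r2(r2_hi, S), ne_from_r2(max(r2_lo, 0), S))
  }
  # parametric: chi-square on the mean r2 with df = total comparisons
  df <- sum(pair_k)
  r2_lo_p <- r2_mean * df / stats::qchisq(0.975, df)
  r2_hi_p <- r2_mean * df / stats::qchisq(0.025, df)
  ci_p <- c(ne_from_r2(r2_hi_p, S), ne_from_r2(r2_lo_p, S))
  structure(list(ne = ne, r2 = r2_mean,
                 expected_r2 = 1 / (S - 1) + 1.1 / S^2,
                 r2_drift = r2_mean - (1 / (S - 1) + 1.1 / S^2),
                 ci_jackknife = sort(ci_j), ci_parametric = sort(ci_p),
                 S = S, n_pairs = length(pair_r2), n_comparisons = df,
                 maf = maf, group = group),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.0f", v), "inf")
  cat(sprintf(
    "LD-Ne (%s): %s (jackknife 95%% CI %s-%s, parametric %s-%s; S=%.1f, %d locus pairs)\n",
    x$group, fmt(x$ne), fmt(x$ci_jackknife[1]), fmt(x$ci_jackknife[2]),
    fmt(x$ci_parametric[1]), fmt(x$ci_parametric[2]), x$S, x$n_pairs))
  invisible(x)
}

#' Long-term effective size from heterozygosity
#'
#' Mutation-drift equilibrium inversion of expected heterozygosity under
#' the stepwise mutation model, Ne = ((1/(1-H))^2 - 1) / (8 mu), and the
#' infinite-alleles model, Ne = H / (4 mu (1-H)), plus their mean and
#' standard deviation per rate.
#'
#' @param H expected heterozygosity in [0, 1).
#' @param mu per-locus per-generation mutation rate(s); may be a vector.
#' @return data frame per mu: Ne_SMM, Ne_IAM, mean, sd.
#' @export
longterm_ne_het <- function(H, mu) {
  if (H < 0 || H >= 1) stop("H must lie in [0, 1)")
  res <- lapply(mu, function(m) {
    smm <- ((1 / (1 - H))^2 - 1) / (8 * m)
    iam <- H / (4 * m * (1 - H))
    data.frame(mu = m, Ne_SMM = smm, Ne_IAM = iam,
               mean = mean(c(smm, iam)), sd = stats::sd(c(smm, iam)))
  })
  do.call(rbind, res)
}

#' Long-term female effective size from mitochondrial theta
#'
#' Inverts theta = 2 Ne u for the maternally inherited marker: NEf =
#' theta / (2u), reported for each supplied per-sequence per-generation
#' substitution rate.
#'
#' @param theta_seq Watterson's theta per sequence.
#' @param u per-sequence per-generation mutation rate(s).
#' @return data frame per u with NEf.
#' @export
female_ne_from_theta <- function(theta_seq, u) {
  stopifnot(theta_seq >= 0, all(u > 0))
  data.frame(u = u, NEf = theta_seq / (2 * u))
}
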