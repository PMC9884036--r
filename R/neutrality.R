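#' Tajima's D from summary quantities
#'
#' Standard Tajima (1989) statistic contrasting nucleotide diversity with
#' Watterson's theta. Negative values indicate an excess of rare variants
#' (expansion or purifying selection); positive values an excess of
#' intermediate-frequency variants.
#'
#' @param n number of sequences (>= 4).
#' @param S number of segregating sites.
#' @param pi_seq mean number of pairwise differences per sequence.
#' @return the D statistic; `NA` with attribute `undefined = TRUE` when
#'   S = 0.
#' @export
tajimas_d <- function(n, S, pi_seq) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S == 0) return(structure(NA_real_, undefined = TRUE))
  A1 <- a1(n); A2 <- a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / A1
  c2 <- b2 - (n + 2) / (A1 * n) + A2 / A1^2
  e1 <- c1 / A1
  e2 <- c2 / (A1^2 + A2)
  (pi_seq - S / A1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Tajima's D for an alignment
#'
#' Convenience wrapper computing S and pi under complete deletion via
#' [mt_diversity_summary()].
#'
#' @param aln a `dna_alignment`.
#' @return the D statistic.
#' @export
tajimas_d_aln <- function(aln) {
  s <- mt_diversity_summary(aln)
  tajimas_d(s$n, s$S, s$pi_seq)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n),
# computed by the stable log-space recurrence s(n,k) = s(n-1,k-1) + (n-1) s(n-1,k)
log_stirling_row <- function(n) {
  prev <- 0 # row 1: s(1,1) = 1
  for (m in 2:n) {
    cur <- numeric(m)
    # k = 1: s(m,1) = (m-1)!
    cur[1] <- prev[1] + log(m - 1)
    if (m > 2) {
      for (k in 2:(m - 1)) {
        x <- prev[k - 1]; y <- log(m - 1) + prev[k]
        mx <- max(x, y)
        cur[k] <- mx + log(exp(x - mx) + exp(y - mx))
      }
    }
    cur[m] <- 0 # s(m,m) = 1
    prev <- cur
  }
  prev
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probability mass P(K = k) for the number of distinct alleles (haplotypes)
#' in a sample of n genes under the neutral infinite-alleles model with
#' scaled mutation rate theta, computed from unsigned Stirling numbers of
#' the first kind in log space.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (> 0).
#' @return numeric vector of length n, P(K = 1..n).
#' @export
ewens_k_distribution <- function(n, theta) {
  stopifnot(theta > 0, n >= 1)
  if (n == 1) return(1)
  ls <- log_stirling_row(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Fu's Fs statistic
#'
#' S' = P(K >= k_obs) under the Ewens sampling distribution with theta set
#' to the observed mean pairwise difference (pi per sequence);
#' Fs = ln(S' / (1 - S')). Large negative values indicate an excess of
#' haplotypes relative to neutrality, the signature of population growth.
#'
#' @param n number of sequences.
#' @param k_obs observed number of distinct haplotypes.
#' @param pi_seq mean pairwise differences per sequence (the theta plug-in).
#' @return Fs; `Inf` with attribute `undefined = TRUE` when k_obs = 1
#'   (S' = 1).
#' @export
fus_fs <- function(n, k_obs, pi_seq) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (k_obs == 1) return(structure(Inf, undefined = TRUE))
  if (pi_seq <= 0)
    stop("pi_seq = 0 with more than one haplotype: Fs undefined")
  p <- ewens_k_distribution(n, pi_seq)
  Sp <- sum(p[k_obs:n])
  log(Sp / (1 - Sp))
}

#' Fu's Fs for an alignment
#' @param aln a `dna_alignment`.
#' @return Fs.
#' @export
fus_fs_aln <- function(aln) {
  s <- mt_diversity_summary(aln)
  fus_fs(s$n, s$h, s$pi_seq)
}
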