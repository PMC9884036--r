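#' Collapse an alignment into unique haplotypes with per-group counts
#'
#' Identical sequences (full-string identity) are merged. Haplotype ids are
#' assigned in order of first occurrence (`H01`, `H02`, ...), which makes the
#' collapse deterministic for a given sample order.
#'
#' @param aln a `dna_alignment`.
#' @param part a `pop_partition` covering all samples.
#' @return list of class `haplotype_table`: `haplotypes` (named character
#'   vector id -> sequence), `counts` (haplotype x group integer matrix),
#'   `assignment` (sample id -> haplotype id).
#' @export
collapse_haplotypes <- function(aln, part) {
  part <- part_align(part, aln$samples)
  first <- !duplicated(aln$sequences)
  hseq <- aln$sequences[first]
  ids <- sprintf("H%02d", seq_along(hseq))
  hap_of <- ids[match(aln$sequences, hseq)]
  counts <- table(factor(hap_of, levels = ids), part)
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(ids, levels(part)))
  structure(list(haplotypes = stats::setNames(hseq, ids),
                 counts = counts,
                 assignment = stats::setNames(hap_of, aln$samples)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes over %d samples, %d group(s)\n",
              length(x$haplotypes), sum(x$counts), ncol(x$counts)))
  invisible(x)
}

# columns of the alignment usable for site statistics: complete deletion of
# any site carrying a gap, N, or ambiguity code in any sequence
complete_sites <- function(m) {
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  which(keep)
}

# number of pairwise differences between two character vectors
seq_diff <- function(x, y) sum(x != y)

#' Sequence diversity summary
#'
#' Computes the standard single-population sequence diversity statistics:
#' number of segregating sites S, haplotype diversity Hd with its sampling
#' standard deviation, nucleotide diversity per site (pi) with standard
#' deviation, and Watterson's theta per sequence and per site. Sites with a
#' gap, N, or ambiguity code in any sequence are excluded (complete
#' deletion); the effective length used is reported.
#'
#' Hd uses the n/(n-1) small-sample correction; pi uses the unbiased
#' n(n-1)/2 pairwise denominator; theta_seq = S / a1(n).
#'
#' @param aln a `dna_alignment` with at least two sequences.
#' @return list of class `mt_diversity`: n, h, S, Hd, Hd_sd, pi_site,
#'   pi_sd, pi_seq, theta_site, theta_seq, length_used.
#' @export
mt_diversity_summary <- function(aln) {
  n <- length(aln$samples)
  if (n < 2) stop("need at least 2 sequences")
  m <- aln_matrix(aln)
  keep <- complete_sites(m)
  m <- m[, keep, drop = FALSE]
  L <- length(keep)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  # haplotypes over the retained sites
  hap <- apply(m, 1, paste, collapse = "")
  cnt <- as.integer(table(hap))
  h <- length(cnt)
  p <- cnt / n
  sum2 <- sum(p^2)
  Hd <- n * (1 - sum2) / (n - 1)
  # Nei (1987) eq. 8.12 sampling variance of heterozygosity
  vHd <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sum2^2) + sum2 - sum2^2)
  # mean pairwise differences via site-wise allele counts (O(S) not O(n^2))
  pi_seq <- 0
  for (j in which(apply(m, 2, function(col) length(unique(col)) > 1))) {
    tab <- table(m[, j])
    pi_seq <- pi_seq + (choose(n, 2) - sum(choose(tab, 2))) / choose(n, 2)
  }
  pi_site <- pi_seq / L
  # Tajima (1983)-style total variance of pi per site
  vpi <- (n + 1) * pi_site / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi_site^2 / (9 * n * (n - 1))
  theta_seq <- S / a1(n)
  structure(list(n = n, h = h, S = S,
                 Hd = Hd, Hd_sd = sqrt(max(vHd, 0)),
                 pi_site = pi_site, pi_sd = sqrt(max(vpi, 0)),
                 pi_seq = pi_seq,
                 theta_site = theta_seq / L, theta_seq = theta_seq,
                 length_used = L),
            class = "mt_diversity")
}

#' @export
print.mt_diversity <- function(x, ...) {
  cat(sprintf(
    "n=%d h=%d S=%d Hd=%.3f+/-%.3f pi=%.4f+/-%.4f theta_site=%.4f theta_seq=%.3f (L=%d)\n",
    x$n, x$h, x$S, x$Hd, x$Hd_sd, x$pi_site, x$pi_sd,
    x$theta_site, x$theta_seq, x$length_used))
  invisible(x)
}

#' Haplotype diversity from haplotype counts
#'
#' @param counts integer vector of haplotype counts.
#' @return Hd with the n/(n-1) correction.
#' @export
haplotype_diversity <- function(counts) {
  n <- sum(counts)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Watterson's theta per sequence from n and S
#'
#' @param n number of sequences.
#' @param S number of segregating sites.
#' @return theta per sequence, S / a1(n).
#' @export
watterson_theta_seq <- function(n, S) S / a1(n)

#' Average pairwise divergence within and between groups (Dxy)
#'
#' Between-group entries are the mean number of pairwise differences between
#' members of the two groups; the diagonal holds the within-group mean
#' pairwise difference. Differences are counted over sites where both
#' sequences carry unambiguous bases. Percent divergence divides by the
#' pairwise-complete site count.
#'
#' @param aln a `dna_alignment`.
#' @param part partition with at least 2 groups.
#' @return list with matrices `dxy` and `percent`; within-group values for
#'   singleton groups are `NA`.
#' @export
pairwise_dxy <- function(aln, part) {
  part <- part_align(part, aln$samples)
  m <- aln_matrix(aln)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  n <- nrow(m)
  diffs <- matrix(0, n, n)
  sites <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      diffs[i, j] <- diffs[j, i] <- sum(m[i, use] != m[j, use])
      sites[i, j] <- sites[j, i] <- sum(use)
    }
  }
  gs <- levels(part)
  K <- length(gs)
  if (K < 2) stop("need at least 2 groups")
  dxy <- pct <- matrix(NA_real_, K, K, dimnames = list(gs, gs))
  for (a in seq_len(K)) {
    ia <- which(part == gs[a])
    for (b in a:K) {
      ib <- which(part == gs[b])
      if (a == b) {
        if (length(ia) < 2) next
        pairs <- utils::combn(ia, 2)
        d <- diffs[cbind(pairs[1, ], pairs[2, ])]
        s <- sites[cbind(pairs[1, ], pairs[2, ])]
      } else {
        idx <- expand.grid(ia, ib)
        d <- diffs[cbind(idx[[1]], idx[[2]])]
        s <- sites[cbind(idx[[1]], idx[[2]])]
      }
      dxy[a, b] <- dxy[b, a] <- mean(d)
      pct[a, b] <- pct[b, a] <- 100 * mean(d / s)
    }
  }
  list(dxy = dxy, percent = pct)
}
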