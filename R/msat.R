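# allele count table for one locus within a set of sample indices
allele_counts <- function(gm, locus, idx = seq_along(gm$samples)) {
  a <- c(gm$calls[idx, locus, 1], gm$calls[idx, locus, 2])
  table(a[!is.na(a)])
}

# per-sample dosage matrix for one locus (columns = alleles)
dosage_matrix <- function(gm, locus, idx = seq_along(gm$samples)) {
  a1v <- gm$calls[idx, locus, 1]
  a2v <- gm$calls[idx, locus, 2]
  alleles <- sort(unique(stats::na.omit(c(a1v, a2v))))
  d <- matrix(NA_real_, length(idx), length(alleles),
              dimnames = list(gm$samples[idx], alleles))
  typed <- !is.na(a1v)
  for (k in seq_along(alleles)) {
    d[typed, k] <- (a1v[typed] == alleles[k]) + (a2v[typed] == alleles[k])
  }
  d
}

#' Per-locus, per-group diversity summary
#'
#' Observed heterozygosity, Nei's unbiased expected heterozygosity
#' He = 2n(1 - sum p^2)/(2n - 1) over the 2n typed gene copies, plain gene
#' diversity 1 - sum p^2, the inbreeding coefficient Fis = 1 - Ho/He, and
#' allele counts. Missing genotypes are dropped per locus (pairwise
#' deletion).
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @return data frame with one row per locus x group: group, locus,
#'   n_typed, n_alleles, Ho, He, gene_diversity, Fis. All-missing
#'   locus-group cells are reported with `n_typed = 0` and `NA` statistics.
#' @export
locus_summary <- function(gm, part) {
  part <- part_align(part, gm$samples)
  out <- list()
  for (g in levels(part)) {
    idx <- which(part == g)
    for (l in seq_along(gm$loci)) {
      a1v <- gm$calls[idx, l, 1]; a2v <- gm$calls[idx, l, 2]
      typed <- !is.na(a1v)
      n <- sum(typed)
      if (n == 0) {
        out[[length(out) + 1]] <- data.frame(
          group = g, locus = gm$loci[l], n_typed = 0L, n_alleles = NA_integer_,
          Ho = NA_real_, He = NA_real_, gene_diversity = NA_real_,
          Fis = NA_real_)
        next
      }
      cnt <- allele_counts(gm, l, idx)
      p <- as.numeric(cnt) / sum(cnt)
      Ho <- mean(a1v[typed] != a2v[typed])
      gd <- 1 - sum(p^2)
      He <- 2 * n * gd / (2 * n - 1)
      Fis <- if (He > 0) 1 - Ho / He else NA_real_
      out[[length(out) + 1]] <- data.frame(
        group = g, locus = gm$loci[l], n_typed = n,
        n_alleles = length(cnt), Ho = Ho, He = He, gene_diversity = gd,
        Fis = Fis)
    }
  }
  do.call(rbind, out)
}

# Levene's exact distribution of the heterozygote count for a biallelic
# locus: P(h het | n individuals, nA copies of allele A)
levene_het_distribution <- function(n, nA) {
  nB <- 2 * n - nA
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hs, function(h) {
    nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
    lfactorial(n) - lfactorial(nAA) - lfactorial(nBB) - lfactorial(h) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) + lfactorial(n) -
      lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), hs)
}

#' Exact / Monte-Carlo Hardy-Weinberg test
#'
#' Tests genotype proportions against Hardy-Weinberg expectations using the
#' heterozygote count as statistic and the conditional (Levene) distribution
#' given allele counts. Biallelic loci are evaluated by full enumeration;
#' multi-allelic loci by Monte-Carlo reshuffling of gene copies into
#' genotypes (seeded, `n_perm` replicates). The two-sided p-value sums the
#' probabilities of all heterozygote counts no more probable than the
#' observed one (probability ordering).
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @param locus locus name or index.
#' @param group group label (default: first group); use `NULL` with a
#'   single-group partition.
#' @param n_perm Monte-Carlo replicates (default 10000).
#' @param seed optional integer seed for the Monte-Carlo path.
#' @return p-value (1 for monomorphic loci).
#' @export
hwe_exact_test <- function(gm, part, locus, group = NULL, n_perm = 10000,
                           seed = NULL) {
  part <- part_align(part, gm$samples)
  if (is.null(group)) group <- levels(part)[1]
  idx <- which(part == group)
  l <- if (is.character(locus)) match(locus, gm$loci) else locus
  a1v <- gm$calls[idx, l, 1]; a2v <- gm$calls[idx, l, 2]
  typed <- !is.na(a1v)
  a1v <- a1v[typed]; a2v <- a2v[typed]
  n <- length(a1v)
  copies <- c(a1v, a2v)
  alleles <- unique(copies)
  if (length(alleles) < 2) return(1)
  h_obs <- sum(a1v != a2v)
  if (length(alleles) == 2) {
    nA <- sum(copies == alleles[1])
    p <- levene_het_distribution(n, nA)
    return(sum(p[p <= p[as.character(h_obs)] + 1e-12]))
  }
  mc <- function() vapply(seq_len(n_perm), function(r) {
    perm <- sample(copies)
    sum(perm[seq_len(n)] != perm[n + seq_len(n)])
  }, 0L)
  hs <- if (is.null(seed)) mc() else with_seed(seed, mc())
  tab <- table(hs) / n_perm
  p_obs <- if (as.character(h_obs) %in% names(tab))
    tab[[as.character(h_obs)]] else 0
  sum(tab[tab <= p_obs + 1e-12])
}

#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Log-likelihood-ratio (G) statistic comparing the joint two-locus
#' genotype table to independence of the two single-locus genotype margins,
#' with significance by permutation of one locus' genotypes across
#' individuals within the group.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @param locus_pair length-2 vector of locus names or indices.
#' @param group group label (default first group).
#' @param n_perm permutation replicates (default 2000).
#' @param seed optional seed.
#' @return p-value (1 when either locus is monomorphic in the group).
#' @export
genotypic_ld_test <- function(gm, part, locus_pair, group = NULL,
                              n_perm = 2000, seed = NULL) {
  part <- part_align(part, gm$samples)
  if (is.null(group)) group <- levels(part)[1]
  idx <- which(part == group)
  li <- vapply(locus_pair, function(x)
    if (is.character(x)) match(x, gm$loci) else as.integer(x), 0L)
  g1 <- paste(gm$calls[idx, li[1], 1], gm$calls[idx, li[1], 2])
  g2 <- paste(gm$calls[idx, li[2], 1], gm$calls[idx, li[2], 2])
  ok <- !is.na(gm$calls[idx, li[1], 1]) & !is.na(gm$calls[idx, li[2], 1])
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(unique(g1)) < 2 || length(unique(g2)) < 2) return(1)
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sel <- tab > 0
    2 * sum(tab[sel] * log(tab[sel] / e[sel]))
  }
  obs <- gstat(g1, g2)
  mc <- function() vapply(seq_len(n_perm), function(r)
    gstat(g1, sample(g2)), 0)
  ge <- if (is.null(seed)) mc() else with_seed(seed, mc())
  perm_pvalue(sum(ge >= obs - 1e-12), n_perm)
}

#' Null-allele frequency estimators from homozygote excess
#'
#' Two moment estimators of the frequency of a non-amplifying (null)
#' allele: Chakraborty et al. (1992), r = (He - Ho) / (He + Ho), and
#' Brookfield (1996, eq. 1), r = (He - Ho) / (1 + He) - the pair reported
#' by Micro-Checker-style screens. Both floored at 0 when Ho >= He.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @param locus locus name or index.
#' @param group group label (default first).
#' @return named numeric vector `c(chakraborty =, brookfield =)`.
#' @export
null_allele_frequency <- function(gm, part, locus, group = NULL) {
  ls <- locus_summary(gm, part)
  part <- part_align(part, gm$samples)
  if (is.null(group)) group <- levels(part)[1]
  lname <- if (is.character(locus)) locus else gm$loci[locus]
  row <- ls[ls$group == group & ls$locus == lname, ]
  He <- row$He; Ho <- row$Ho
  if (is.na(He) || He == 0) return(c(chakraborty = 0, brookfield = 0))
  c(chakraborty = max(0, (He - Ho) / (He + Ho)),
    brookfield = max(0, (He - Ho) / (1 + He)))
}

#' Rarefied allelic and private allelic richness
#'
#' Expected number of alleles (and of private alleles) per locus in a
#' random draw of `g` gene copies, by hypergeometric rarefaction:
#' E[A] = sum_a (1 - choose(N - N_a, g) / choose(N, g)). An allele is
#' private to a group when it is present in that group's rarefied draw and
#' absent from every other group's rarefied draw (multi-group
#' generalization with independent draws per group).
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @param g rarefaction size in gene copies.
#' @return data frame per group: mean rarefied allelic richness and private
#'   richness over loci, plus `g`.
#' @export
rarefied_richness <- function(gm, part, g) {
  part <- part_align(part, gm$samples)
  gs <- levels(part)
  L <- length(gm$loci)
  # per locus x group allele count tables
  tabs <- lapply(seq_len(L), function(l)
    lapply(gs, function(gr) allele_counts(gm, l, which(part == gr))))
  for (l in seq_len(L)) for (k in seq_along(gs)) {
    N <- sum(tabs[[l]][[k]])
    if (N < g) stop("group ", gs[k], ", locus ", gm$loci[l],
                    ": only ", N, " gene copies < g = ", g)
  }
  pres <- function(N_a, N) 1 - exp(lchoose(N - N_a, g) - lchoose(N, g))
  res <- lapply(seq_along(gs), function(k) {
    ar <- pr <- numeric(L)
    for (l in seq_len(L)) {
      cnt <- tabs[[l]][[k]]
      N <- sum(cnt)
      p_here <- pres(as.numeric(cnt), N)
      ar[l] <- sum(p_here)
      # absence probability of the same allele size in every other group
      p_abs_other <- vapply(names(cnt), function(a) {
        prod(vapply(seq_along(gs)[-k], function(k2) {
          cnt2 <- tabs[[l]][[k2]]
          N2 <- sum(cnt2)
          n_a2 <- if (a %in% names(cnt2)) cnt2[[a]] else 0
          exp(lchoose(N2 - n_a2, g) - lchoose(N2, g))
        }, 0))
      }, 0)
      pr[l] <- sum(p_here * p_abs_other)
    }
    data.frame(group = gs[k], rarefied_allelic_richness = mean(ar),
               rarefied_private_richness = mean(pr), gene_copies_g = g)
  })
  do.call(rbind, res)
}

#' Locus quality-control filter
#'
#' Flags loci that deviate from Hardy-Weinberg across groups with evidence
#' of null alleles, mirroring the common practice of discarding such
#' markers before structure analyses.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @param alpha per-test significance level after Bonferroni correction
#'   across loci and groups (default 0.05).
#' @param min_null minimum Chakraborty null-frequency estimate counting as
#'   "evidence of nulls" (default 0.1).
#' @param min_groups_failing number of groups in which a locus must fail
#'   HWE to be dropped (default 2).
#' @param seed seed for the Monte-Carlo HWE tests.
#' @return list with `keep` and `drop` locus-name vectors and the per
#'   locus x group p-value matrix (Bonferroni-adjusted).
#' @export
locus_qc_filter <- function(gm, part, alpha = 0.05, min_null = 0.1,
                            min_groups_failing = 2, seed = 1L) {
  part <- part_align(part, gm$samples)
  gs <- levels(part)
  pm <- matrix(NA_real_, length(gm$loci), length(gs),
               dimnames = list(gm$loci, gs))
  nulls <- matrix(NA_real_, length(gm$loci), length(gs),
                  dimnames = list(gm$loci, gs))
  for (l in seq_along(gm$loci)) for (k in seq_along(gs)) {
    pm[l, k] <- hwe_exact_test(gm, part, l, gs[k],
                               seed = stage_seed(seed, paste0("hwe", l, "_", k)))
    nulls[l, k] <- null_allele_frequency(gm, part, l, gs[k])["chakraborty"]
  }
  padj <- matrix(stats::p.adjust(pm, method = "bonferroni"), nrow(pm),
                 dimnames = dimnames(pm))
  fail <- rowSums(padj < alpha & nulls > min_null, na.rm = TRUE)
  drop <- gm$loci[fail >= min_groups_failing]
  list(keep = setdiff(gm$loci, drop), drop = drop, p_adjusted = padj)
}
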