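# Weir & Cockerham (1984) variance components for one locus.
# D: dosage matrix (individuals x alleles, NA rows = untyped),
# grp: factor over rows. Returns per-allele a, b, c components.
wc_components_locus <- function(D, grp) {
  typed <- !is.na(D[, 1])
  D <- D[typed, , drop = FALSE]
  grp <- droplevels(grp[typed])
  r <- nlevels(grp)
  if (r < 2 || nrow(D) == 0) return(NULL)
  ni <- as.numeric(table(grp))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  gi <- as.integer(grp)
  A <- ncol(D)
  a <- b <- cc <- numeric(A)
  for (k in seq_len(A)) {
    x <- D[, k]
    pi <- tapply(x, gi, sum) / (2 * ni)
    hi <- tapply(x == 1, gi, mean)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    if (nbar <= 1 || nc <= 0) next
    a[k] <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[k] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[k] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

# list of per-locus WC components for a genotype matrix
wc_components <- function(gm, part) {
  part <- part_align(part, gm$samples)
  comp <- vector("list", length(gm$loci))
  for (l in seq_along(gm$loci)) {
    D <- dosage_matrix(gm, l)
    comp[[l]] <- wc_components_locus(D, part)
  }
  names(comp) <- gm$loci
  comp[!vapply(comp, is.null, TRUE)]
}

wc_from_components <- function(comp) {
  A <- sum(vapply(comp, function(x) sum(x$a), 0))
  B <- sum(vapply(comp, function(x) sum(x$b), 0))
  C <- sum(vapply(comp, function(x) sum(x$c), 0))
  c(Fis = 1 - C / (B + C), Fst = A / (A + B + C), Fit = 1 - C / (A + B + C))
}

#' Weir-Cockerham global F-statistics
#'
#' Multilocus Fis, Fst and Fit as ratios of summed Weir & Cockerham (1984)
#' variance components (a, b, c) over alleles and loci, with 95% confidence
#' intervals by bootstrap over loci.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition` with >= 2 groups.
#' @param n_boot bootstrap replicates over loci (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return list with `estimates` (named vector Fis, Fst, Fit), `ci` (2 x 3
#'   matrix of percentile bounds), and per-locus component sums.
#' @export
wc_f_statistics <- function(gm, part, n_boot = 1000, seed = 1L) {
  part <- part_align(part, gm$samples)
  if (nlevels(part) < 2) stop("Fst undefined for a single group")
  comp <- wc_components(gm, part)
  est <- wc_from_components(comp)
  bt <- with_seed(seed, t(vapply(seq_len(n_boot), function(r) {
    wc_from_components(comp[sample(length(comp), replace = TRUE)])
  }, c(Fis = 0, Fst = 0, Fit = 0))))
  ci <- apply(bt, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
  list(estimates = est, ci = ci,
       per_locus = t(vapply(comp, function(x)
         c(a = sum(x$a), b = sum(x$b), c = sum(x$c)), c(a = 0, b = 0, c = 0))))
}

# pairwise WC theta for two groups, from a genotype matrix restricted to
# the pair's samples
wc_pair_theta <- function(gm, part, g1, g2) {
  part <- part_align(part, gm$samples)
  idx <- which(part %in% c(g1, g2))
  sub <- gm_subset(gm, idx)
  subpart <- pop_partition(stats::setNames(as.character(part[idx]),
                                           sub$samples))
  unname(wc_from_components(wc_components(sub, subpart))["Fst"])
}

#' Pairwise Fst matrix with permutation p-values
#'
#' Microsatellite pairs use the Weir-Cockerham theta restricted to the two
#' groups; mitochondrial data (passed as a `dna_alignment`) use PhiST from
#' pairwise sequence differences (two-level AMOVA). p-values are the
#' fraction of sample-label permutations with a statistic at least as large
#' as observed.
#'
#' @param data a `genotype_matrix` or a `dna_alignment`.
#' @param part a `pop_partition` with >= 2 groups.
#' @param n_perm permutations per pair (default 999).
#' @param seed integer seed.
#' @return list of class `fst_matrix`: `values`, `p_values` (symmetric
#'   matrices, diagonal 0 / NA), `marker`.
#' @export
pairwise_fst_matrix <- function(data, part, n_perm = 999, seed = 1L) {
  is_seq <- inherits(data, "dna_alignment")
  samples <- if (is_seq) data$samples else data$samples
  part <- part_align(part, samples)
  gs <- levels(part)
  K <- length(gs)
  if (K < 2) stop("need at least 2 groups")
  vals <- pv <- matrix(NA_real_, K, K, dimnames = list(gs, gs))
  diag(vals) <- 0
  if (is_seq) dmat <- pairwise_diff_matrix(data)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ia <- which(part == gs[a]); ib <- which(part == gs[b])
    if (length(ia) < 2 || length(ib) < 2) next
    idx <- c(ia, ib)
    lab <- factor(rep(c("A", "B"), c(length(ia), length(ib))))
    if (is_seq) {
      dsub <- dmat[idx, idx]
      stat <- function(l) phist_from_dist(dsub, l)
    } else {
      # precompute dosage matrices once; permutations only relabel groups
      Dlist <- lapply(seq_along(data$loci), function(l)
        dosage_matrix(data, l, idx))
      stat <- function(l) {
        A <- B <- C <- 0
        for (D in Dlist) {
          cm <- wc_components_locus(D, l)
          if (is.null(cm)) next
          A <- A + sum(cm$a); B <- B + sum(cm$b); C <- C + sum(cm$c)
        }
        A / (A + B + C)
      }
    }
    obs <- stat(lab)
    if (!is.finite(obs)) next # no variation in the pair: undefined
    ge <- with_seed(stage_seed(seed, paste0("fstpair", a, "_", b)), {
      g <- 0L
      for (r in seq_len(n_perm)) {
        sp <- stat(sample(lab))
        if (is.finite(sp) && sp >= obs - 1e-12) g <- g + 1L
      }
      g
    })
    vals[a, b] <- vals[b, a] <- obs
    pv[a, b] <- pv[b, a] <- perm_pvalue(ge, n_perm)
  }
  structure(list(values = vals, p_values = pv,
                 marker = if (is_seq) "mtDNA" else "microsatellite",
                 corrected = FALSE),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("fst_matrix (%s%s):\n", x$marker,
              if (isTRUE(x$corrected)) ", ENA-corrected" else ""))
  print(round(x$values, 4))
  invisible(x)
}

# EM estimate of the null-allele frequency for one locus in one group,
# treating observed homozygotes as mixtures of true homozygotes and null
# heterozygotes, and untyped individuals as null homozygotes (HWE within
# group assumed). Returns the estimated null frequency and adjusted
# visible-allele frequencies (summing to 1 - p_null).
em_null_freq <- function(counts_hom, counts_het_allele, n_missing = 0,
                         max_iter = 1000, tol = 1e-9) {
  # counts_hom: named vector, observed homozygote individuals per allele
  # counts_het_allele: named vector, allele copies seen in heterozygotes
  alleles <- union(names(counts_hom), names(counts_het_allele))
  hom <- stats::setNames(numeric(length(alleles)), alleles)
  het <- hom
  hom[names(counts_hom)] <- counts_hom
  het[names(counts_het_allele)] <- counts_het_allele
  n_ind <- sum(hom) + sum(het) / 2 + n_missing
  pn <- max(0.01, sqrt(n_missing / n_ind))
  q <- (2 * hom + het)
  q <- q / sum(q) * (1 - pn) # unconditional visible frequencies
  for (it in seq_len(max_iter)) {
    # E: expected fraction of each observed-homozygote class that is a
    # null heterozygote: 2 q_a pn / (q_a^2 + 2 q_a pn)
    w <- 2 * pn / (q + 2 * pn)
    w[q == 0] <- 0
    null_copies <- sum(hom * w) + 2 * n_missing
    vis_copies <- 2 * hom * (1 - w) + hom * w + het
    q_new <- vis_copies / (2 * n_ind)
    pn_new <- null_copies / (2 * n_ind)
    if (max(abs(c(q_new - q, pn_new - pn))) < tol ||
        (pn_new < 1e-6 && n_missing == 0)) { # boundary: no null signal
      return(list(p_null = pn_new, p_visible = q_new, converged = TRUE))
    }
    q <- q_new; pn <- pn_new
  }
  list(p_null = pn, p_visible = q, converged = FALSE)
}

#' ENA-corrected pairwise Fst matrix
#'
#' Estimates a per-locus, per-group null-allele frequency by EM (observed
#' homozygote classes treated as mixtures of true homozygotes and null
#' heterozygotes under within-group HWE), then recomputes pairwise Fst from
#' the corrected visible-allele frequencies, excluding the null size class
#' (the "excluding null alleles" correction). Falls back to the uncorrected
#' value with a warning when the EM does not converge for any locus.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @return an `fst_matrix` with `corrected = TRUE`; also carries
#'   `null_freq` (locus x group EM estimates).
#' @export
ena_corrected_fst <- function(gm, part) {
  part <- part_align(part, gm$samples)
  gs <- levels(part)
  K <- length(gs)
  L <- length(gm$loci)
  nulls <- matrix(0, L, K, dimnames = list(gm$loci, gs))
  freqs <- vector("list", L) # per locus: list of per-group corrected freqs
  sizes <- matrix(0, L, K)
  any_nonconv <- FALSE
  for (l in seq_len(L)) {
    freqs[[l]] <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- which(part == gs[k])
      A1 <- gm$calls[idx, l, 1]; A2 <- gm$calls[idx, l, 2]
      typed <- !is.na(A1)
      A1 <- A1[typed]; A2 <- A2[typed]
      sizes[l, k] <- length(A1)
      homo <- A1 == A2
      ch <- table(factor(A1[homo]))
      ha <- table(factor(c(A1[!homo], A2[!homo])))
      if (length(A1) == 0) next
      fit <- em_null_freq(as.vector(ch) |> stats::setNames(names(ch)),
                          as.vector(ha) |> stats::setNames(names(ha)),
                          n_missing = sum(!typed))
      if (!fit$converged) any_nonconv <- TRUE
      nulls[l, k] <- fit$p_null
      freqs[[l]][[k]] <- fit$p_visible
    }
  }
  if (any_nonconv)
    warning("EM did not converge for at least one locus; uncorrected frequencies used there")
  vals <- matrix(NA_real_, K, K, dimnames = list(gs, gs))
  diag(vals) <- 0
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    vals[a, b] <- vals[b, a] <- ena_pair_theta(freqs, sizes, a, b)
  }
  structure(list(values = vals, p_values = matrix(NA_real_, K, K,
                                                  dimnames = list(gs, gs)),
                 marker = "microsatellite", corrected = TRUE,
                 null_freq = nulls),
            class = "fst_matrix")
}

# ratio-of-sums pairwise theta from corrected frequencies
ena_pair_theta <- function(freqs, sizes, a, b) {
  num <- den <- 0
  for (l in seq_along(freqs)) {
    pa <- freqs[[l]][[a]]; pb <- freqs[[l]][[b]]
    if (is.null(pa) || is.null(pb)) next
    alle <- union(names(pa), names(pb))
    # unconditional corrected visible frequencies: each row sums to
    # 1 - p_null for its group; the null size class itself is excluded
    # from the allele sum (the "excluding null alleles" estimator)
    P <- rbind(ifelse(alle %in% names(pa), pa[alle], 0),
               ifelse(alle %in% names(pb), pb[alle], 0))
    ni <- sizes[l, c(a, b)]
    r <- 2
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    # a/(a+b+c) decomposition with the HWE-expected heterozygosity, since
    # genotype-level heterozygosity is unobservable after the correction
    for (k in seq_len(ncol(P))) {
      pk <- P[, k]
      pbar <- sum(ni * pk) / (r * nbar)
      s2 <- sum(ni * (pk - pbar)^2) / ((r - 1) * nbar)
      hbar <- 2 * pbar * (1 - pbar) # HWE expectation after correction
      aa <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      bb <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cx <- hbar / 2
      num <- num + aa
      den <- den + aa + bb + cx
    }
  }
  num / den
}
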