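# Fixture builders and independent brute-force oracles shared across tests.

# genotype matrix from a list of per-sample genotype strings like
# "150/152 200/200", one locus per whitespace-separated token
make_gm <- function(rows, ids = NULL, motif = 2L) {
  geno <- lapply(rows, function(r) strsplit(strsplit(r, "\\s+")[[1]], "/"))
  L <- length(geno[[1]])
  n <- length(rows)
  calls <- array(NA_integer_, c(n, L, 2))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- geno[[i]][[l]]
    if (!identical(g, c("NA", "NA")) && g[1] != "NA") {
      calls[i, l, 1] <- as.integer(g[1])
      calls[i, l, 2] <- as.integer(g[2])
    }
  }
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  genotype_matrix(calls, ids, sprintf("L%02d", seq_len(L)),
                  rep(motif, L))
}

# draw diploid genotypes at HWE from given allele frequencies
gm_from_freqs <- function(freq_list_per_group, n_per_group, motif = 2L) {
  # freq_list_per_group: list(group = list(locus = named freq vector))
  groups <- names(freq_list_per_group)
  L <- length(freq_list_per_group[[1]])
  ntot <- sum(n_per_group)
  calls <- array(NA_integer_, c(ntot, L, 2))
  ids <- character(ntot)
  grp <- character(ntot)
  i0 <- 0
  for (g in seq_along(groups)) {
    n <- n_per_group[g]
    for (l in seq_len(L)) {
      f <- freq_list_per_group[[g]][[l]]
      alle <- as.integer(names(f))
      calls[i0 + seq_len(n), l, 1] <- sample(alle, n, TRUE, prob = f)
      calls[i0 + seq_len(n), l, 2] <- sample(alle, n, TRUE, prob = f)
    }
    ids[i0 + seq_len(n)] <- sprintf("%s_%03d", groups[g], seq_len(n))
    grp[i0 + seq_len(n)] <- groups[g]
    i0 <- i0 + n
  }
  list(gm = genotype_matrix(calls, ids, sprintf("L%02d", seq_len(L)),
                            rep(motif, L)),
       part = pop_partition(stats::setNames(grp, ids)))
}

rand_alignment <- function(n, L, n_var = max(1, L %/% 10)) {
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(base, n), n, L, byrow = TRUE)
  var_sites <- sample(L, n_var)
  for (s in var_sites) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), base[s]), 1)
    carriers <- sample(n, sample(n - 1, 1))
    m[carriers, s] <- alt
  }
  seqs <- apply(m, 1, paste, collapse = "")
  dna_alignment(stats::setNames(seqs, sprintf("t%03d", seq_len(n))))
}

# brute-force pi (mean pairwise differences) and S by explicit loops over
# all sequence pairs, complete-deletion sites only
brute_pi_S <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  list(pi_seq = tot / choose(n, 2), S = S, L = ncol(m))
}

# literal transcription of the Weir & Cockerham (1984) estimator for one
# locus, looping over alleles with scalar arithmetic; genotypes given as a
# data frame with columns a1, a2 (integers, no missing), pop (factor)
wc_oracle_locus <- function(df) {
  pops <- levels(df$pop)
  r <- length(pops)
  ni <- sapply(pops, function(p) sum(df$pop == p))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(c(df$a1, df$a2)))
  A <- B <- C <- 0
  for (al in alleles) {
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      sub <- df[df$pop == pops[k], ]
      p_i[k] <- (sum(sub$a1 == al) + sum(sub$a2 == al)) / (2 * nrow(sub))
      h_i[k] <- mean((sub$a1 == al) != (sub$a2 == al))
    }
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; B <- B + b; C <- C + cc
  }
  c(Fst = A / (A + B + C), Fis = 1 - C / (B + C), Fit = 1 - C / (A + B + C))
}

# brute-force two-level AMOVA from a squared-distance matrix: literal sums
# of squares and the expected-mean-square solution
amova2_oracle <- function(d2, grp) {
  grp <- droplevels(as.factor(grp))
  N <- nrow(d2); K <- nlevels(grp)
  sst <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) sst <- sst + d2[i, j]
  sst <- sst / N
  ssw <- 0
  for (g in levels(grp)) {
    idx <- which(grp == g)
    acc <- 0
    if (length(idx) > 1)
      for (i in seq_along(idx)[-length(idx)])
        for (j in (i + 1):length(idx)) acc <- acc + d2[idx[i], idx[j]]
    ssw <- ssw + acc / length(idx)
  }
  ssa <- sst - ssw
  ng <- sapply(levels(grp), function(g) sum(grp == g))
  msa <- ssa / (K - 1); msw <- ssw / (N - K)
  n_eff <- (N - sum(ng^2) / N) / (K - 1)
  s2w <- msw; s2a <- (msa - msw) / n_eff
  list(ssa = ssa, ssw = ssw, s2a = s2a, s2w = s2w,
       phi_st = s2a / (s2a + s2w))
}

# exhaustive rarefaction oracle: mean distinct alleles over all
# combinations of g copies drawn from the observed multiset
rarefy_enum <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  combs <- utils::combn(length(copies), g)
  mean(apply(combs, 2, function(ix) length(unique(copies[ix]))))
}

# neutral infinite-sites coalescent sample: returns list(S, pi_seq, k)
coalescent_neutral_sample <- function(n, theta) {
  # genealogy identical in law to the Kingman process; mutations Poisson
  # theta/2 per branch; infinite sites: each mutation is a new column
  members <- as.list(seq_len(n))
  k <- n
  mut_carriers <- list()
  while (k > 1) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    nm <- stats::rpois(k, theta / 2 * t_k)
    for (ln in which(nm > 0))
      for (z in seq_len(nm[ln]))
        mut_carriers[[length(mut_carriers) + 1]] <- members[[ln]]
    pair <- sample.int(k, 2)
    members[[pair[1]]] <- c(members[[pair[1]]], members[[pair[2]]])
    members[[pair[2]]] <- NULL
    k <- k - 1
  }
  S <- length(mut_carriers)
  if (S == 0) return(list(S = 0, pi_seq = 0, k = 1))
  geno <- matrix(0L, n, S)
  for (s in seq_len(S)) geno[mut_carriers[[s]], s] <- 1L
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(geno[i, ] != geno[j, ])
  hap <- apply(geno, 1, paste, collapse = "")
  list(S = S, pi_seq = tot / choose(n, 2), k = length(unique(hap)))
}
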