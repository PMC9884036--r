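#' Modified Garza-Williamson M-ratio
#'
#' Per locus, alleles are converted to repeat units via the locus motif
#' length; k is the number of occupied size classes and r the allele-size
#' range in repeat units; M = k / (r + 1) (the modified form whose
#' denominator counts all size classes spanned, inclusive). Bottlenecked
#' populations lose size classes inside the range, depressing M.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @param group group label (default first).
#' @param include_monomorphic include M = 1 loci in the mean (default
#'   FALSE; they carry no range information).
#' @return list of class `m_ratio_result`: `per_locus` data frame (locus,
#'   k, r, M), `mean`, `sd`, `n_loci`.
#' @export
m_ratio <- function(gm, part, group = NULL, include_monomorphic = FALSE) {
  part <- part_align(part, gm$samples)
  if (is.null(group)) group <- levels(part)[1]
  idx <- which(part == group)
  rows <- list()
  for (l in seq_along(gm$loci)) {
    sizes <- stats::na.omit(c(gm$calls[idx, l, ]))
    if (!length(sizes)) next
    motif <- gm$motif_length[l]
    units <- round((sizes - min(sizes)) / motif)
    k <- length(unique(units))
    r <- max(units)
    M <- k / (r + 1)
    rows[[length(rows) + 1]] <- data.frame(
      locus = gm$loci[l], k = k, r = r, M = M, monomorphic = k == 1)
  }
  tab <- do.call(rbind, rows)
  used <- if (include_monomorphic) tab else tab[!tab$monomorphic, ]
  structure(list(per_locus = tab, mean = mean(used$M),
                 sd = stats::sd(used$M), n_loci = nrow(used),
                 group = group),
            class = "m_ratio_result")
}

#' @export
print.m_ratio_result <- function(x, ...) {
  cat(sprintf("M-ratio (%s): %.3f +/- %.3f over %d polymorphic loci\n",
              x$group, x$mean, x$sd, x$n_loci))
  invisible(x)
}

# one coalescent replicate of mean M over loci for n_genes gene copies
# under the two-phase mutation model at scaled rate theta; each locus is
# conditioned on polymorphism, matching the empirical M which is computed
# over observed polymorphic loci. Mutations are placed as a zero-truncated
# Poisson count on the genealogy's stored branch segments (same law as a
# per-branch Poisson process conditioned on >= 1 mutation), so small theta
# does not require rejection over whole genealogies.
critical_m_replicate <- function(n_genes, n_loci, theta, p_multistep,
                                 mean_step) {
  m_vals <- numeric(n_loci)
  ks <- n_genes:2
  for (l in seq_len(n_loci)) {
    repeat {
      lineages <- as.list(seq_len(n_genes))
      t_int <- numeric(n_genes - 1)
      seg_sets <- vector("list", n_genes - 1)
      for (i in seq_along(ks)) {
        k <- ks[i]
        t_int[i] <- stats::rexp(1, rate = k * (k - 1) / 2)
        seg_sets[[i]] <- lineages
        pair <- sample.int(k, 2)
        lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
        lineages[[pair[2]]] <- NULL
      }
      lambda <- theta / 2 * sum(ks * t_int)
      p0 <- stats::ppois(0, lambda)
      M <- stats::qpois(p0 + stats::runif(1) * (1 - p0), lambda)
      if (M < 1) M <- 1
      sizes <- integer(n_genes)
      iv <- sample.int(length(ks), M, replace = TRUE, prob = ks * t_int)
      st <- tpm_steps(M, p_multistep, mean_step)
      for (m in seq_len(M)) {
        set <- seg_sets[[iv[m]]][[sample.int(ks[iv[m]], 1)]]
        sizes[set] <- sizes[set] + st[m]
      }
      units <- sizes - min(sizes)
      kk <- length(unique(units))
      if (kk > 1) break # cancellation left the locus monomorphic: redraw
    }
    m_vals[l] <- kk / (max(units) + 1)
  }
  mean(m_vals)
}

#' Critical M by coalescent simulation
#'
#' Simulates the equilibrium distribution of the mean M-ratio for a sample
#' of `n_genes` gene copies at `n_loci` independent loci: each locus draws
#' a Kingman coalescent genealogy, mutations are placed as Poisson events
#' at rate theta/2 per unit branch length, and each mutation moves the
#' allele size by one repeat unit with probability 1 - p_multistep, else by
#' a geometric number of units (conditioned >= 2) with mean `mean_step`.
#' Each locus is conditioned on polymorphism, mirroring the empirical
#' M-ratio which is taken over observed polymorphic loci.
#' The critical value Mc is the 5th percentile of the replicate
#' distribution of mean M: equilibrium data fall below it 5% of the time.
#'
#' @param n_genes gene copies per locus.
#' @param n_loci loci per replicate.
#' @param theta scaled mutation rate (per locus); may be a vector (a grid).
#' @param p_multistep probability of a multi-step mutation (default 0.2).
#' @param mean_step mean size of multi-step changes in repeat units
#'   (default 3.5).
#' @param reps replicates (>= 1000 recommended for reported values).
#' @param seed integer seed.
#' @return data frame per theta: Mc (5th percentile), mean_M, sd_M, reps.
#' @export
critical_m <- function(n_genes, n_loci, theta, p_multistep = 0.2,
                       mean_step = 3.5, reps = 2000, seed = 1L) {
  res <- lapply(theta, function(th) {
    ms <- with_seed(stage_seed(seed, paste0("critm", th)),
      vapply(seq_len(reps), function(r)
        critical_m_replicate(n_genes, n_loci, th, p_multistep, mean_step),
        0))
    data.frame(theta = th,
               Mc = unname(stats::quantile(ms, 0.05)),
               mean_M = mean(ms), sd_M = stats::sd(ms), reps = reps)
  })
  do.call(rbind, res)
}
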