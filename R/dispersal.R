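#' Corrected assignment indices (AIc)
#'
#' For each individual, AI is the sum over typed loci of the log10 expected
#' Hardy-Weinberg frequency of its genotype in its own group, with allele
#' frequencies computed excluding the focal individual (leave-one-out).
#' Alleles unseen in the rest of the group receive the pseudo-frequency
#' 1/(2 n_group + 1) to avoid log(0). AIc subtracts the group mean AI, so
#' AIc sums to zero within every group; residents score high, immigrants
#' low.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition`.
#' @return data frame: sample_id, group, n_typed_loci, AI, AIc.
#'   Individuals missing at all loci are excluded.
#' @export
assignment_indices <- function(gm, part) {
  part <- part_align(part, gm$samples)
  N <- length(gm$samples)
  L <- length(gm$loci)
  AI <- numeric(N)
  typed_loci <- integer(N)
  for (g in levels(part)) {
    idx <- which(part == g)
    ng <- length(idx)
    for (l in seq_len(L)) {
      a1v <- gm$calls[idx, l, 1]; a2v <- gm$calls[idx, l, 2]
      typed <- which(!is.na(a1v))
      if (length(typed) == 0) next
      cnt <- table(c(a1v[typed], a2v[typed]))
      tot <- sum(cnt)
      pseudo <- 1 / (2 * ng + 1)
      for (i in typed) {
        x <- a1v[i]; y <- a2v[i]
        # leave-one-out counts
        cx <- cnt[[as.character(x)]] - (x == x) - (y == x)
        cy <- cnt[[as.character(y)]] - (x == y) - (y == y)
        den <- tot - 2
        px <- if (den > 0 && cx > 0) cx / den else pseudo
        py <- if (den > 0 && cy > 0) cy / den else pseudo
        f <- if (x == y) px^2 else 2 * px * py
        AI[idx[i]] <- AI[idx[i]] + log10(f)
        typed_loci[idx[i]] <- typed_loci[idx[i]] + 1L
      }
    }
  }
  keep <- typed_loci > 0
  df <- data.frame(sample_id = gm$samples, group = as.character(part),
                   n_typed_loci = typed_loci, AI = AI,
                   stringsAsFactors = FALSE)[keep, ]
  mu <- tapply(df$AI, df$group, mean)
  df$AIc <- df$AI - mu[df$group]
  rownames(df) <- NULL
  df
}

# Queller-Goodnight pairwise relatedness matrix within groups, referenced
# to the group's allele frequencies; symmetrized estimator
qg_relatedness_matrix <- function(gm, part) {
  part <- part_align(part, gm$samples)
  N <- length(gm$samples)
  R <- matrix(NA_real_, N, N, dimnames = list(gm$samples, gm$samples))
  for (g in levels(part)) {
    idx <- which(part == g)
    L <- length(gm$loci)
    num_xy <- den_x <- matrix(0, length(idx), length(idx))
    for (l in seq_len(L)) {
      a1v <- gm$calls[idx, l, 1]; a2v <- gm$calls[idx, l, 2]
      typed <- !is.na(a1v)
      if (sum(typed) < 2) next
      cnt <- table(c(a1v[typed], a2v[typed]))
      p <- as.numeric(cnt) / sum(cnt)
      names(p) <- names(cnt)
      for (ii in seq_along(idx)) {
        if (!typed[ii]) next
        for (jj in seq_along(idx)) {
          if (jj == ii || !typed[jj]) next
          ax <- c(a1v[ii], a2v[ii]); ay <- c(a1v[jj], a2v[jj])
          px <- p[as.character(ax)]
          hom <- as.numeric(ax[1] == ax[2])
          num_xy[ii, jj] <- num_xy[ii, jj] +
            0.5 * (sum(ax[1] == ay) + sum(ax[2] == ay)) - px[1] - px[2]
          den_x[ii, jj] <- den_x[ii, jj] + 1 + hom - px[1] - px[2]
        }
      }
    }
    r_dir <- num_xy / den_x
    r_sym <- (r_dir + t(r_dir)) / 2
    R[idx, idx] <- r_sym
    diag(R[idx, idx]) <- NA_real_
  }
  R
}

# per-sex WC Fst/Fis from dosage data restricted to one sex
sex_wc <- function(gm, part, sel) {
  sub <- gm_subset(gm, sel)
  sp <- pop_partition(stats::setNames(as.character(part[sel]), sub$samples),
                      levels = levels(part))
  est <- wc_from_components(wc_components(sub, sp))
  est[c("Fst", "Fis")]
}

# mean observed heterozygosity and within-group gene diversity for a sex
sex_ho_hs <- function(gm, part, sel) {
  sub <- gm_subset(gm, sel)
  sp <- part_align(part, sub$samples)
  ls <- locus_summary(sub, sp)
  c(Ho = mean(ls$Ho, na.rm = TRUE), Hs = mean(ls$He, na.rm = TRUE))
}

#' Sex-biased dispersal test suite
#'
#' Computes, per sex: mean and variance of corrected assignment indices
#' (mAIc, vAIc), Weir-Cockerham Fst and Fis, mean Queller-Goodnight
#' relatedness over within-group dyads, observed heterozygosity Ho and
#' within-group gene diversity Hs. One-sided significance by randomizing
#' sex labels within groups, oriented a priori toward the dispersing-sex
#' signature: lower mAIc, higher vAIc, lower Fst, higher Fis, lower
#' relatedness, and higher Hs for the dispersing sex.
#'
#' @param gm a `genotype_matrix`.
#' @param part a `pop_partition` (groups within which dispersal is tested).
#' @param sexes named character vector sample_id -> "F"/"M" ("U" excluded).
#' @param dispersing_sex which sex the alternative designates as dispersing
#'   (default "M").
#' @param n_rand randomizations for the assignment-index metrics
#'   (default 10000).
#' @param n_rand_heavy randomizations for the metrics that must be
#'   recomputed per draw (Fst, Fis, relatedness, Ho, Hs); default
#'   `min(n_rand, 1000)`.
#' @param metrics subset of c("mAIc","vAIc","Fst","Fis","relatedness",
#'   "Ho","Hs") to compute (default all).
#' @param seed integer seed.
#' @return list of class `sex_bias_result`: `table` (metric x sex values),
#'   `p_one_sided` named vector, `n` per sex.
#' @export
sex_bias_test_suite <- function(gm, part, sexes, dispersing_sex = "M",
                                n_rand = 10000,
                                n_rand_heavy = min(n_rand, 1000),
                                metrics = c("mAIc", "vAIc", "Fst", "Fis",
                                            "relatedness", "Ho", "Hs"),
                                seed = 1L) {
  part <- part_align(part, gm$samples)
  sex <- sexes[gm$samples]
  keep <- !is.na(sex) & sex %in% c("F", "M")
  # groups must contain both sexes
  both <- vapply(levels(part), function(g)
    all(c("F", "M") %in% sex[keep & part == g]), TRUE)
  excluded <- levels(part)[!both]
  keep <- keep & part %in% levels(part)[both]
  gm2 <- gm_subset(gm, which(keep))
  part2 <- part_align(part, gm2$samples)
  sex2 <- factor(sex[keep], levels = c("F", "M"))
  ns <- table(sex2)
  if (any(ns < 3)) stop("need >= 3 individuals of each sex")
  other <- setdiff(c("F", "M"), dispersing_sex)

  ai <- assignment_indices(gm2, part2)
  aic <- stats::setNames(ai$AIc, ai$sample_id)[gm2$samples]
  R <- if ("relatedness" %in% metrics) qg_relatedness_matrix(gm2, part2)

  obs <- calc_sub(gm2, part2, sex2, aic, R, metrics)

  # one-sided statistic per metric: dispersing-sex value minus the other,
  # with the rejection direction per metric
  direction <- c(mAIc = -1, vAIc = +1, Fst = -1, Fis = +1,
                 relatedness = -1, Ho = -1, Hs = +1)
  stat <- (obs[, dispersing_sex] - obs[, other]) * direction[rownames(obs)]

  heavy <- c("Fst", "Fis", "relatedness", "Ho", "Hs")
  nr_heavy <- min(n_rand, n_rand_heavy)
  count_ge <- stats::setNames(integer(nrow(obs)), rownames(obs))
  nrep <- stats::setNames(integer(nrow(obs)), rownames(obs))
  rng_state <- if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  set.seed(stage_seed(seed, "sexbias"))
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
  for (r in seq_len(n_rand)) {
    sx <- sex2
    for (g in levels(part2)) {
      i <- which(part2 == g)
      sx[i] <- sample(sx[i])
    }
    mets <- rownames(obs)
    if (r > nr_heavy) mets <- setdiff(mets, heavy)
    if (!length(mets)) break
    prm <- calc_sub(gm2, part2, sx, aic, R, mets)
    st <- (prm[, dispersing_sex] - prm[, other]) * direction[mets]
    count_ge[mets] <- count_ge[mets] + as.integer(st >= stat[mets] - 1e-12)
    nrep[mets] <- nrep[mets] + 1L
  }
  p <- (count_ge + 1) / (nrep + 1)
  structure(list(table = obs, p_one_sided = p, n = ns,
                 dispersing_sex = dispersing_sex,
                 excluded_groups = excluded),
            class = "sex_bias_result")
}

# metric computation for a (possibly permuted) sex factor; shares the
# precomputed AIc values and relatedness matrix
calc_sub <- function(gm2, part2, sx, aic, R, metrics) {
  out <- list()
  for (s in c("F", "M")) {
    sel <- which(sx == s)
    v <- c()
    if ("mAIc" %in% metrics) v["mAIc"] <- mean(aic[sel], na.rm = TRUE)
    if ("vAIc" %in% metrics) v["vAIc"] <- stats::var(aic[sel], na.rm = TRUE)
    if (any(c("Fst", "Fis") %in% metrics)) {
      wc <- sex_wc(gm2, part2, sel)
      if ("Fst" %in% metrics) v["Fst"] <- wc["Fst"]
      if ("Fis" %in% metrics) v["Fis"] <- wc["Fis"]
    }
    if ("relatedness" %in% metrics) {
      same <- outer(sx == s, sx == s, "&") &
        outer(as.integer(part2), as.integer(part2), "==")
      diag(same) <- FALSE
      v["relatedness"] <- mean(R[same], na.rm = TRUE)
    }
    if (any(c("Ho", "Hs") %in% metrics)) {
      hh <- sex_ho_hs(gm2, part2, sel)
      if ("Ho" %in% metrics) v["Ho"] <- hh["Ho"]
      if ("Hs" %in% metrics) v["Hs"] <- hh["Hs"]
    }
    out[[s]] <- v
  }
  cbind(F = out$F, M = out$M)
}

#' @export
print.sex_bias_result <- function(x, ...) {
  cat("sex-biased dispersal tests (one-sided toward", x$dispersing_sex,
      "dispersal)\n")
  print(round(x$table, 4))
  cat("p (one-sided): ",
      paste(names(x$p_one_sided), round(x$p_one_sided, 4), sep = "=",
            collapse = "  "), "\n")
  invisible(x)
}
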