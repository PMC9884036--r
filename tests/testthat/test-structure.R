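test_that("WC F-statistics match the literal-formula oracle to 1e-12", {
  set.seed(61)
  for (r in 1:5) {
    # tiny dataset: 2 groups x 4 diploids x 1 locus, alleles from 3 sizes
    a <- sample(c(100L, 104L, 108L), 16, TRUE)
    calls <- array(a, c(8, 1, 2))
    gm <- genotype_matrix(calls, sprintf("i%d", 1:8), "L1", 2L)
    part <- pop_partition(stats::setNames(rep(c("x", "y"), each = 4),
                                          gm$samples))
    df <- data.frame(a1 = pmin(a[1:8], a[9:16]),
                     a2 = pmax(a[1:8], a[9:16]),
                     pop = factor(rep(c("x", "y"), each = 4)))
    if (length(unique(c(df$a1, df$a2))) < 2) next
    oracle <- wc_oracle_locus(df)
    est <- wc_f_statistics(gm, part, n_boot = 10, seed = 1)$estimates
    expect_equal(unname(est["Fst"]), unname(oracle["Fst"]),
                 tolerance = 1e-12)
    expect_equal(unname(est["Fis"]), unname(oracle["Fis"]),
                 tolerance = 1e-12)
    expect_equal(unname(est["Fit"]), unname(oracle["Fit"]),
                 tolerance = 1e-12)
  }
})

test_that("WC Fst hits the boundary cases", {
  # identical allele frequencies at HWE: theta near 0
  set.seed(62)
  f <- list(a = list(L1 = stats::setNames(c(.5, .5), c(100, 104)),
                     L2 = stats::setNames(c(.3, .7), c(200, 208))),
            b = list(L1 = stats::setNames(c(.5, .5), c(100, 104)),
                     L2 = stats::setNames(c(.3, .7), c(200, 208))))
  d <- gm_from_freqs(f, c(100, 100))
  est <- wc_f_statistics(d$gm, d$part, n_boot = 50, seed = 2)$estimates
  expect_lt(abs(est["Fst"]), 0.02)

  # groups fixed for different alleles: Fst = 1
  gm <- make_gm(c("100/100", "100/100", "108/108", "108/108"))
  part <- pop_partition(stats::setNames(c("a", "a", "b", "b"), gm$samples))
  est2 <- wc_f_statistics(gm, part, n_boot = 10, seed = 1)$estimates
  expect_equal(unname(est2["Fst"]), 1, tolerance = 1e-12)

  expect_error(wc_f_statistics(gm, pop_partition(
    stats::setNames(rep("a", 4), gm$samples))), "single group")
})

test_that("pairwise Fst restricted to two groups equals the global value", {
  set.seed(63)
  cfg <- sim_config(n_demes = 3, deme_sizes = c(60, 60, 60),
                    sample_sizes = c(20, 20, 20), sites_per_deme = c(2, 2, 2),
                    burn_in = 200, seed = 5)
  sim <- simulate_dataset(cfg)
  gm <- sim$genotypes; part <- sim$partition
  fm <- pairwise_fst_matrix(gm, part, n_perm = 49, seed = 9)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    gs <- levels(part)[pair]
    idx <- which(part %in% gs)
    sub <- gm_subset(gm, idx)
    subpart <- pop_partition(stats::setNames(
      as.character(part[idx]), sub$samples))
    direct <- wc_f_statistics(sub, subpart, n_boot = 10,
                              seed = 1)$estimates["Fst"]
    expect_equal(unname(fm$values[gs[1], gs[2]]), unname(direct),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(fm$values))
  expect_true(all(diag(fm$values) == 0))
})

test_that("a duplicated panmictic group shows Fst near 0 with large p", {
  set.seed(64)
  f <- list(g = list(L1 = stats::setNames(c(.4, .6), c(100, 104)),
                     L2 = stats::setNames(c(.2, .3, .5), c(200, 204, 208))))
  d <- gm_from_freqs(f, 120)
  half <- rep(c("u", "v"), each = 60)
  part <- pop_partition(stats::setNames(half, d$gm$samples))
  fm <- pairwise_fst_matrix(d$gm, part, n_perm = 199, seed = 3)
  expect_lt(abs(fm$values["u", "v"]), 0.02)
  expect_gt(fm$p_values["u", "v"], 0.1)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  set.seed(65)
  f <- list(a = list(L1 = stats::setNames(c(.8, .2), c(100, 104))),
            b = list(L1 = stats::setNames(c(.2, .8), c(100, 104))))
  d <- gm_from_freqs(f, c(30, 30))
  f1 <- pairwise_fst_matrix(d$gm, d$part, n_perm = 99, seed = 42)
  f2 <- pairwise_fst_matrix(d$gm, d$part, n_perm = 99, seed = 42)
  expect_identical(f1$p_values, f2$p_values)
})

test_that("ENA correction is identity without nulls, shrinks Fst with them", {
  set.seed(66)
  # no nulls: corrected matches uncorrected to 3 decimals
  f <- list(a = list(L1 = stats::setNames(c(.7, .3), c(100, 104)),
                     L2 = stats::setNames(c(.5, .5), c(200, 204))),
            b = list(L1 = stats::setNames(c(.3, .7), c(100, 104)),
                     L2 = stats::setNames(c(.5, .5), c(200, 204))))
  d <- gm_from_freqs(f, c(150, 150))
  fm <- pairwise_fst_matrix(d$gm, d$part, n_perm = 49, seed = 1)
  fe <- ena_corrected_fst(d$gm, d$part)
  expect_equal(fe$values["a", "b"], fm$values["a", "b"], tolerance = 5e-3)

  # with nulls: naive Fst inflated, corrected moves back toward truth
  mk_null <- function(n, shift) {
    vis <- c(100, 104, 108) + shift
    p <- c(0.5, 0.2, 0.1, 0.2) # last class is the null
    a1 <- sample(c(vis, -1), n, TRUE, prob = p)
    a2 <- sample(c(vis, -1), n, TRUE, prob = p)
    bn <- a1 == -1 & a2 == -1
    v1 <- ifelse(a1 == -1, a2, a1); v2 <- ifelse(a2 == -1, a1, a2)
    v1[bn] <- NA; v2[bn] <- NA
    cbind(v1, v2)
  }
  closer <- shrunk <- logical(30)
  for (r in 1:30) {
    n <- 100
    calls_t <- array(NA_integer_, c(2 * n, 4, 2)) # truth: nulls visible
    calls_o <- array(NA_integer_, c(2 * n, 4, 2)) # observed
    for (l in 1:4) {
      vis <- c(100, 104, 108)
      p_a <- c(0.5, 0.2, 0.1, 0.2)
      p_b <- c(0.2, 0.5, 0.1, 0.2)
      a1a <- sample(c(vis, 90), n, TRUE, prob = p_a)
      a2a <- sample(c(vis, 90), n, TRUE, prob = p_a)
      a1b <- sample(c(vis, 90), n, TRUE, prob = p_b)
      a2b <- sample(c(vis, 90), n, TRUE, prob = p_b)
      calls_t[, l, 1] <- c(a1a, a1b); calls_t[, l, 2] <- c(a2a, a2b)
      hide <- function(x, y) {
        bn <- x == 90 & y == 90
        v <- ifelse(x == 90, y, x); v[bn] <- NA; v
      }
      calls_o[, l, 1] <- c(hide(a1a, a2a), hide(a1b, a2b))
      calls_o[, l, 2] <- c(hide(a2a, a1a), hide(a2b, a1b))
    }
    ids <- sprintf("i%03d", 1:(2 * n))
    grp <- rep(c("a", "b"), each = n)
    gm_t <- genotype_matrix(calls_t, ids, paste0("L", 1:4), rep(2L, 4))
    gm_o <- genotype_matrix(calls_o, ids, paste0("L", 1:4), rep(2L, 4))
    part <- pop_partition(stats::setNames(grp, ids))
    truth <- wc_f_statistics(gm_t, part, n_boot = 2, seed = 1)$estimates["Fst"]
    naive <- wc_f_statistics(gm_o, part, n_boot = 2, seed = 1)$estimates["Fst"]
    corr <- ena_corrected_fst(gm_o, part)$values["a", "b"]
    shrunk[r] <- corr <= naive + 1e-9
    closer[r] <- abs(corr - truth) <= abs(naive - truth) + 1e-9
  }
  expect_gte(mean(shrunk), 0.8)
  expect_gt(mean(closer), 0.5)
})

test_that("AMOVA matches the brute-force SSD oracle and sums to 100%", {
  # 3-group sequence toy
  seqs <- c(g1a = "AAAAAAAA", g1b = "AAAAAAAT", g2a = "TTTTAAAA",
            g2b = "TTTTAAAT", g3a = "TTTTTTTT", g3b = "TTTTTTTA",
            g3c = "TTTTTTAA")
  part <- pop_partition(stats::setNames(
    c("g1", "g1", "g2", "g2", "g3", "g3", "g3"), names(seqs)))
  aln <- dna_alignment(seqs)
  am <- amova(aln, part, n_perm = 99, seed = 1)
  d2 <- pairwise_diff_matrix(aln)
  oracle <- amova2_oracle(d2, part)
  expect_equal(am$components$SSD[1], oracle$ssa, tolerance = 1e-12)
  expect_equal(am$components$SSD[2], oracle$ssw, tolerance = 1e-12)
  expect_equal(am$components$variance,
               c(oracle$s2a, oracle$s2w), tolerance = 1e-12)
  expect_equal(unname(am$phi["Phi_ST"]), oracle$phi_st, tolerance = 1e-12)
  expect_equal(sum(am$components$percent), 100, tolerance = 0.01)
  expect_equal(sum(am$components$percent_truncated), 100, tolerance = 0.01)
})

test_that("AMOVA hits the extreme cases", {
  # identical sequences within groups, differing between: ~100% among
  seqs <- stats::setNames(c(rep("AAAAAAAA", 4), rep("TTTTTTTT", 4)),
                          sprintf("s%d", 1:8))
  part <- pop_partition(stats::setNames(rep(c("a", "b"), each = 4),
                                        names(seqs)))
  am <- amova(dna_alignment(seqs), part, n_perm = 99, seed = 2)
  expect_gt(am$components$percent[1], 99)
  expect_lte(am$p_values["Phi_ST"], 0.05)

  # random split of a panmictic group: among-group ~0, p large
  set.seed(67)
  aln <- rand_alignment(30, 100, n_var = 12)
  part2 <- pop_partition(stats::setNames(
    sample(rep(c("u", "v"), 15)), aln$samples))
  am2 <- amova(aln, part2, n_perm = 199, seed = 3)
  expect_lt(abs(am2$components$percent[1]), 15)
  expect_gt(am2$p_values["Phi_ST"], 0.05)
})

test_that("microsatellite AMOVA agrees with its gene-copy SSD oracle", {
  set.seed(68)
  f <- list(a = list(L1 = stats::setNames(c(.8, .2), c(100, 104)),
                     L2 = stats::setNames(c(.6, .4), c(200, 204))),
            b = list(L1 = stats::setNames(c(.2, .8), c(100, 104)),
                     L2 = stats::setNames(c(.4, .6), c(200, 204))))
  d <- gm_from_freqs(f, c(8, 8))
  am <- amova(d$gm, d$part, n_perm = 49, seed = 1)
  expect_equal(sum(am$components$percent), 100, tolerance = 0.01)
  # oracle: total SSD over gene copies equals the fit's total
  d2 <- archipop:::copy_distance_matrix(d$gm, "identity")
  Nc <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / Nc
  expect_equal(sum(am$components$SSD), sst, tolerance = 1e-9)
  # two-group mtDNA PhiST equals the pairwise matrix value
  aln <- rand_alignment(16, 60, n_var = 10)
  part <- pop_partition(stats::setNames(rep(c("x", "y"), each = 8),
                                        aln$samples))
  am_mt <- amova(aln, part, n_perm = 49, seed = 2)
  fm <- pairwise_fst_matrix(aln, part, n_perm = 49, seed = 2)
  expect_equal(unname(am_mt$phi["Phi_ST"]), fm$values["x", "y"],
               tolerance = 1e-12)
})

test_that("PCA separates fixed clusters and is invariant to sample order", {
  gm <- make_gm(c(rep("100/100 200/200", 5), rep("108/108 208/208", 5)))
  pca <- run_pca(gm)
  side <- pca$scores[, 1] > 0
  expect_true(all(side[1:5]) || all(!side[1:5]))
  expect_true(all(side[1:5] != side[6:10]))

  set.seed(69)
  f <- list(g = list(L1 = stats::setNames(c(.3, .3, .4), c(100, 104, 108)),
                     L2 = stats::setNames(c(.5, .5), c(200, 204))))
  d <- gm_from_freqs(f, 40)
  p1 <- run_pca(d$gm)
  ord <- sample(40)
  p2 <- run_pca(gm_subset(d$gm, ord))
  expect_equal(abs(p2$scores[d$gm$samples[ord], 1]),
               abs(p1$scores[d$gm$samples[ord], 1]), tolerance = 1e-8)
  expect_true(all(diff(p1$percent_variance) <= 1e-9))
})

test_that("DAPC discriminates structured groups and validates n_pcs", {
  set.seed(70)
  f <- list(a = list(L1 = stats::setNames(c(.9, .1), c(100, 104)),
                     L2 = stats::setNames(c(.8, .2), c(200, 204)),
                     L3 = stats::setNames(c(.7, .3), c(300, 304))),
            b = list(L1 = stats::setNames(c(.1, .9), c(100, 104)),
                     L2 = stats::setNames(c(.2, .8), c(200, 204)),
                     L3 = stats::setNames(c(.3, .7), c(300, 304))))
  d <- gm_from_freqs(f, c(40, 40))
  dap <- run_dapc(d$gm, d$part, n_pcs = 3)
  grp_means <- tapply(dap$scores[, 1], d$part[rownames(dap$scores)], mean)
  expect_gt(abs(diff(grp_means)), 1)
  expect_error(run_dapc(d$gm, d$part, n_pcs = 1000), "rank")
})

test_that("Mantel test recovers identity and respects the permutation null", {
  set.seed(71)
  pts <- cbind(runif(8), runif(8))
  d <- as.matrix(stats::dist(pts))
  res <- mantel_test(d, d, n_perm = 199, seed = 1)
  expect_equal(res$mantel_r, 1, tolerance = 1e-12)
  expect_equal(res$mantel_p, 1 / 200, tolerance = 1e-12)

  d2 <- as.matrix(stats::dist(cbind(runif(8), runif(8))))
  res2 <- mantel_test(d, d2, n_perm = 199, seed = 2)
  expect_true(res2$mantel_p >= 0 && res2$mantel_p <= 1)

  expect_error(mantel_test(matrix(1, 4, 4), d[1:4, 1:4]), "constant")
})

test_that("IBD regression matches closed-form OLS and flat data give b ~ 0", {
  fst <- matrix(0, 4, 4)
  km <- matrix(0, 4, 4)
  pairs <- list(c(2, 1), c(3, 1), c(4, 1), c(3, 2), c(4, 2), c(4, 3))
  fvals <- c(0.02, 0.05, 0.08, 0.03, 0.06, 0.04)
  kvals <- c(170, 340, 500, 180, 350, 175)
  for (i in seq_along(pairs)) {
    fst[pairs[[i]][1], pairs[[i]][2]] <- fvals[i]
    fst[pairs[[i]][2], pairs[[i]][1]] <- fvals[i]
    km[pairs[[i]][1], pairs[[i]][2]] <- kvals[i]
    km[pairs[[i]][2], pairs[[i]][1]] <- kvals[i]
  }
  res <- ibd_regression(fst, km)
  y <- fvals / (1 - fvals); x <- log(kvals)
  b_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$slope, b_hand, tolerance = 1e-12)

  flat <- matrix(0.05, 4, 4); diag(flat) <- 0
  res2 <- ibd_regression(flat, km)
  expect_equal(res2$slope, 0, tolerance = 1e-10)
})

test_that("stepping-stone simulations show positive IBD signals", {
  set.seed(72)
  # 4 demes in a chain with nearest-neighbor migration only
  M <- matrix(0, 4, 4)
  for (i in 1:3) { M[i, i + 1] <- 0.004; M[i + 1, i] <- 0.004 }
  cfg <- sim_config(n_demes = 4, deme_sizes = rep(80, 4), migration = M,
                    sample_sizes = rep(25, 4), sites_per_deme = rep(3, 4),
                    burn_in = 400, seed = 21)
  sim <- simulate_dataset(cfg)
  fm <- pairwise_fst_matrix(sim$genotypes, sim$partition, n_perm = 49,
                            seed = 2)
  centers <- cfg$deme_centers
  km <- site_distance_matrix(data.frame(site_id = levels(sim$partition),
                                        lat = centers$lat,
                                        lon = centers$lon))
  res <- ibd_regression(fm, km, gm = sim$genotypes, part = sim$partition,
                        n_boot = 100, seed = 3)
  expect_gt(res$slope, 0)
  expect_gt(res$ci[1], 0)
  # site-level Mantel over the same structure
  mres <- site_ibd_mantel(sim$genotypes, sim$metadata, n_perm = 199,
                          seed = 4)
  expect_gt(mres$mantel_r, 0)
  expect_lte(mres$mantel_p, 0.05)
})
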