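test_that("locus summaries compute Ho, He, gene diversity and Fis", {
  gm <- make_gm(c("11/12", "11/12"))
  part <- pop_partition(stats::setNames(rep("g", 2), gm$samples))
  ls <- locus_summary(gm, part)
  expect_equal(ls$Ho, 1)
  expect_equal(ls$He, 2 / 3, tolerance = 1e-12) # 2n(1-sum p^2)/(2n-1), p = .5
  expect_lt(ls$Fis, 0)
  expect_equal(ls$Fis, 1 - 1 / (2 / 3), tolerance = 1e-12)

  # monomorphic locus
  gm2 <- make_gm(c("10/10", "10/10", "10/10"))
  ls2 <- locus_summary(gm2, pop_partition(
    stats::setNames(rep("g", 3), gm2$samples)))
  expect_equal(ls2$Ho, 0)
  expect_equal(ls2$He, 0)
  expect_true(is.na(ls2$Fis))

  # all-missing locus-group reported absent, not zero
  gm3 <- make_gm(c("10/10 NA/NA", "10/12 NA/NA"))
  ls3 <- locus_summary(gm3, pop_partition(
    stats::setNames(rep("g", 2), gm3$samples)))
  expect_equal(ls3$n_typed[2], 0)
  expect_true(is.na(ls3$He[2]))
})

test_that("He is invariant to allele relabeling and |Ho-He| shrinks at HWE", {
  set.seed(41)
  f <- list(g = list(L1 = stats::setNames(c(.3, .3, .4), c(100, 104, 108))))
  d <- gm_from_freqs(f, 400)
  ls <- locus_summary(d$gm, d$part)
  # relabel alleles (shift all sizes)
  gm2 <- genotype_matrix(d$gm$calls + 50L, d$gm$samples, d$gm$loci,
                         d$gm$motif_length)
  ls2 <- locus_summary(gm2, d$part)
  expect_equal(ls$He, ls2$He, tolerance = 1e-12)
  expect_lt(abs(ls$Ho - ls$He), 0.06) # large-n HWE draw
  # Fis identity where defined
  expect_equal(ls$Fis, 1 - ls$Ho / ls$He, tolerance = 1e-12)
})

test_that("HWE exact test detects heterozygote deficit and is seeded", {
  # (AA=5, aa=5): full enumeration via the Levene distribution
  gm <- make_gm(c(rep("10/10", 5), rep("12/12", 5)))
  part <- pop_partition(stats::setNames(rep("g", 10), gm$samples))
  p <- hwe_exact_test(gm, part, 1)
  expect_lte(p, 0.01)

  # near-perfect HWE proportions at large n: large p
  set.seed(4)
  f <- list(g = list(L1 = stats::setNames(c(.5, .5), c(100, 102))))
  d <- gm_from_freqs(f, 500)
  expect_gt(hwe_exact_test(d$gm, d$part, 1), 0.2)

  # monomorphic: p = 1
  gmm <- make_gm(c("10/10", "10/10"))
  expect_equal(hwe_exact_test(gmm, pop_partition(
    stats::setNames(rep("g", 2), gmm$samples)), 1), 1)

  # multi-allelic Monte-Carlo path is reproducible under a seed
  f3 <- list(g = list(L1 = stats::setNames(rep(.2, 5),
                                           c(100, 102, 104, 106, 108))))
  d3 <- gm_from_freqs(f3, 60)
  p1 <- hwe_exact_test(d3$gm, d3$part, 1, n_perm = 2000, seed = 11)
  p2 <- hwe_exact_test(d3$gm, d3$part, 1, n_perm = 2000, seed = 11)
  expect_identical(p1, p2)
})

test_that("the Levene distribution is a proper distribution", {
  p <- archipop:::levene_het_distribution(10, 10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # n=2, nA=2: P(h=0)=1/3, P(h=2)=2/3
  p2 <- archipop:::levene_het_distribution(2, 2)
  expect_equal(unname(p2[c("0", "2")]), c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("genotypic LD test flags duplicated loci and passes independence", {
  set.seed(17)
  f <- list(g = list(L1 = stats::setNames(c(.4, .6), c(100, 104))))
  d <- gm_from_freqs(f, 80)
  # duplicate the locus: maximal dependence
  calls <- array(NA_integer_, c(80, 2, 2))
  calls[, 1, ] <- d$gm$calls[, 1, ]
  calls[, 2, ] <- d$gm$calls[, 1, ] + 100L
  gm2 <- genotype_matrix(calls, d$gm$samples, c("L1", "L2"), c(2L, 2L))
  p_dup <- genotypic_ld_test(gm2, d$part, c(1, 2), n_perm = 2000, seed = 3)
  expect_lte(p_dup, 0.001)

  # independent loci: non-significant in a single draw
  f2 <- list(g = list(L1 = stats::setNames(c(.4, .6), c(100, 104)),
                      L2 = stats::setNames(c(.5, .5), c(200, 204))))
  d2 <- gm_from_freqs(f2, 100)
  p_ind <- genotypic_ld_test(d2$gm, d2$part, c(1, 2), n_perm = 999, seed = 5)
  expect_gt(p_ind, 0.05)

  # monomorphic member: p = 1
  gmm <- make_gm(c("10/10 20/22", "10/10 20/20"))
  expect_equal(genotypic_ld_test(gmm, pop_partition(
    stats::setNames(rep("g", 2), gmm$samples)), c(1, 2)), 1)
})

test_that("null-allele estimators respond to homozygote excess", {
  # Ho == He: near-zero estimates
  set.seed(23)
  f <- list(g = list(L1 = stats::setNames(rep(.25, 4),
                                          c(100, 104, 108, 112))))
  d <- gm_from_freqs(f, 500)
  est <- null_allele_frequency(d$gm, d$part, 1)
  expect_lt(est["chakraborty"], 0.05)

  # Ho > He: floored at zero
  gm2 <- make_gm(c("10/12", "10/12", "10/12", "10/12"))
  est2 <- null_allele_frequency(gm2, pop_partition(
    stats::setNames(rep("g", 4), gm2$samples)), 1)
  expect_equal(unname(est2), c(0, 0))

  # a true null allele at frequency 0.2 is recovered near 0.2 at n = 100
  set.seed(29)
  vis <- c(100, 104, 108)
  reps <- replicate(20, {
    p <- c(rep(0.8 / 3, 3), 0.2) # fourth allele is the null
    a1 <- sample(c(vis, -1), 100, TRUE, prob = p)
    a2 <- sample(c(vis, -1), 100, TRUE, prob = p)
    both_null <- a1 == -1 & a2 == -1
    vis1 <- ifelse(a1 == -1, a2, a1) # null heterozygotes look homozygous
    vis2 <- ifelse(a2 == -1, a1, a2)
    vis1[both_null] <- NA; vis2[both_null] <- NA
    calls <- array(c(vis1, vis2), c(100, 1, 2))
    gm <- genotype_matrix(calls, sprintf("i%03d", 1:100), "L1", 2L)
    part <- pop_partition(stats::setNames(rep("g", 100), gm$samples))
    null_allele_frequency(gm, part, 1)["chakraborty"]
  })
  expect_gt(mean(reps >= 0.1 & reps <= 0.3), 0.7)
  expect_lt(abs(mean(reps) - 0.2), 0.07)
})

test_that("hypergeometric rarefaction matches identity and hand arithmetic", {
  # g = N returns the observed allele count
  gm <- make_gm(c("10/12", "12/14", "10/10"))
  part <- pop_partition(stats::setNames(rep("g", 3), gm$samples))
  r <- rarefied_richness(gm, part, 6)
  expect_equal(r$rarefied_allelic_richness, 3, tolerance = 1e-12)

  # counts (8,2), g = 2: E[A] = 2 - C(2,2)/C(10,2) - C(8,2)/C(10,2)
  gm2 <- make_gm(c(rep("10/10", 4), "12/12"))
  part2 <- pop_partition(stats::setNames(rep("g", 5), gm2$samples))
  r2 <- rarefied_richness(gm2, part2, 2)
  expect_equal(r2$rarefied_allelic_richness, 2 - 1 / 45 - 28 / 45,
               tolerance = 1e-12)

  # error names the offending group and locus when g exceeds copies
  expect_error(rarefied_richness(gm2, part2, 11), "only 10 gene copies")
})

test_that("rarefaction equals exhaustive enumeration for N <= 12", {
  set.seed(8)
  for (r in 1:5) {
    counts <- as.vector(stats::rmultinom(1, sample(8:12, 1),
                                         rep(1 / 3, 3)))
    counts <- counts[counts > 0]
    N <- sum(counts)
    g <- sample(2:(N - 1), 1)
    # build a single-locus genotype matrix with these allele counts
    copies <- rep(seq_along(counts) * 4L + 100L, counts)
    if (N %% 2 == 1) { copies <- c(copies, copies[1]); counts[1] <- counts[1] + 1; N <- N + 1 }
    calls <- array(copies, c(N / 2, 1, 2))
    gm <- genotype_matrix(calls, sprintf("i%02d", 1:(N / 2)), "L1", 2L)
    part <- pop_partition(stats::setNames(rep("g", N / 2), gm$samples))
    got <- rarefied_richness(gm, part, g)$rarefied_allelic_richness
    cnt <- table(c(gm$calls[, 1, ]))
    expect_equal(got, rarefy_enum(as.vector(cnt), g), tolerance = 1e-10)
  }
})

test_that("private richness is zero for shared alleles, positive for private", {
  gm <- make_gm(c("10/10", "10/12", "10/10", "10/14"))
  part <- pop_partition(stats::setNames(c("a", "a", "b", "b"), gm$samples))
  r <- rarefied_richness(gm, part, 3)
  # allele 12 private to a, allele 14 private to b, allele 10 shared
  expect_true(all(r$rarefied_private_richness > 0))
  expect_true(all(r$rarefied_private_richness <
                    r$rarefied_allelic_richness))

  # fully shared panel: private richness near zero
  f <- list(a = list(L1 = stats::setNames(c(.5, .5), c(100, 104))),
            b = list(L1 = stats::setNames(c(.5, .5), c(100, 104))))
  set.seed(2)
  d <- gm_from_freqs(f, c(50, 50))
  r2 <- rarefied_richness(d$gm, d$part, 20)
  expect_lt(max(r2$rarefied_private_richness), 0.2)
})

test_that("locus QC filter drops loci failing HWE with nulls across groups", {
  set.seed(55)
  # two clean loci + one locus with a strong null allele in both groups
  n <- 120
  mk_null_locus <- function(n) {
    vis <- c(100, 104, 108)
    p <- c(rep(0.65 / 3, 3), 0.35)
    a1 <- sample(c(vis, -1), n, TRUE, prob = p)
    a2 <- sample(c(vis, -1), n, TRUE, prob = p)
    bn <- a1 == -1 & a2 == -1
    v1 <- ifelse(a1 == -1, a2, a1); v2 <- ifelse(a2 == -1, a1, a2)
    v1[bn] <- NA; v2[bn] <- NA
    cbind(v1, v2)
  }
  mk_clean_locus <- function(n) {
    alle <- c(200, 204, 208, 212)
    cbind(sample(alle, n, TRUE), sample(alle, n, TRUE))
  }
  calls <- array(NA_integer_, c(n, 3, 2))
  calls[, 1, ] <- mk_clean_locus(n)
  calls[, 2, ] <- mk_null_locus(n)
  calls[, 3, ] <- mk_clean_locus(n)
  gm <- genotype_matrix(calls, sprintf("i%03d", 1:n),
                        c("clean1", "nully", "clean2"), rep(2L, 3))
  part <- pop_partition(stats::setNames(
    rep(c("a", "b"), each = n / 2), gm$samples))
  qc <- locus_qc_filter(gm, part, seed = 5)
  expect_true("nully" %in% qc$drop)
  expect_false(any(c("clean1", "clean2") %in% qc$drop))
})
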