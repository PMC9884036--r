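test_that("haplotype collapse merges identical sequences with counts", {
  seqs <- c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAT")
  part <- pop_partition(stats::setNames(rep("g1", 4), names(seqs)))
  tab <- collapse_haplotypes(dna_alignment(seqs), part)
  expect_equal(length(tab$haplotypes), 2)
  expect_equal(unname(tab$counts[, "g1"]), c(3L, 1L))
  expect_equal(unname(tab$assignment[c("a", "d")]), c("H01", "H02"))

  # all-distinct sequences stay distinct
  al2 <- rand_alignment(6, 40, n_var = 20)
  while (length(unique(al2$sequences)) < 6) al2 <- rand_alignment(6, 40, 20)
  p2 <- pop_partition(stats::setNames(rep("g", 6), al2$samples))
  expect_equal(length(collapse_haplotypes(al2, p2)$haplotypes), 6)
})

test_that("a 316-sequence set built from 22 templates recovers 22 haplotypes", {
  set.seed(22)
  base <- rand_alignment(1, 657)$sequences
  templates <- character(22)
  for (h in 1:22) {
    s <- strsplit(base, "")[[1]]
    pos <- sample(657, h + 3) # distinct mutation sets per template
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    templates[h] <- paste(s, collapse = "")
  }
  stopifnot(length(unique(templates)) == 22)
  counts <- as.vector(stats::rmultinom(1, 316 - 22, rep(1 / 22, 22))) + 1
  seqs <- rep(templates, counts)
  ids <- sprintf("ind%03d", seq_along(seqs))
  demes <- sample(c("H", "M", "O", "K"), length(seqs), TRUE)
  tab <- collapse_haplotypes(
    dna_alignment(stats::setNames(seqs, ids)),
    pop_partition(stats::setNames(demes, ids), levels = c("H", "M", "O", "K")))
  expect_equal(length(tab$haplotypes), 22)
  expect_equal(sum(tab$counts), 316)
})

test_that("diversity summary reproduces the published worked values", {
  # n=16 with haplotype counts {15,1}: Hd = 0.125, and S=3 gives
  # theta_seq = 0.904
  base <- strrep("A", 657)
  alt <- paste0("TTT", strrep("A", 654)) # 3 segregating sites
  seqs <- stats::setNames(c(rep(base, 15), alt), sprintf("k%02d", 1:16))
  s <- mt_diversity_summary(dna_alignment(seqs))
  expect_equal(s$n, 16)
  expect_equal(s$h, 2)
  expect_equal(s$S, 3)
  expect_equal(s$Hd, 0.125, tolerance = 1e-12)
  expect_equal(round(s$theta_seq, 3), 0.904)

  expect_equal(round(watterson_theta_seq(16, 20), 3), 6.027)
  expect_equal(round(watterson_theta_seq(47, 6), 3), 1.358)
  expect_equal(round(watterson_theta_seq(92, 25), 3), 4.908)
  # n=2: a1 = 1 so theta equals S
  expect_equal(watterson_theta_seq(2, 5), 5)
  expect_error(mt_diversity_summary(dna_alignment(c(x = "ACGT"))), "at least 2")
})

test_that("closed forms match the brute-force pairwise oracle", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(4:20, 1)
    aln <- rand_alignment(n, 100, n_var = sample(3:12, 1))
    s <- mt_diversity_summary(aln)
    o <- brute_pi_S(aln)
    expect_equal(s$S, o$S)
    expect_equal(s$pi_seq, o$pi_seq, tolerance = 1e-12)
    expect_equal(s$theta_seq, o$S / sum(1 / seq_len(n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("Hd is invariant to sample order and sites with N are excluded", {
  aln <- rand_alignment(12, 80, n_var = 6)
  s1 <- mt_diversity_summary(aln)
  perm <- sample(12)
  s2 <- mt_diversity_summary(aln_subset(aln, perm))
  expect_equal(s1$Hd, s2$Hd, tolerance = 1e-12)
  expect_equal(s1$pi_seq, s2$pi_seq, tolerance = 1e-12)

  # corrupting one sequence with N at a variable site removes that site
  m <- aln$sequences
  varsite <- which(apply(do.call(rbind, strsplit(m, "")), 2,
                         function(x) length(unique(x)) > 1))[1]
  substr(m[1], varsite, varsite) <- "N"
  s3 <- mt_diversity_summary(dna_alignment(
    stats::setNames(m, aln$samples)))
  expect_equal(s3$length_used, 79)
  expect_lte(s3$S, s1$S)
})

test_that("dxy between and within groups behaves as expected", {
  # two groups fixed for sequences differing at 4 of 100 sites
  a <- strrep("A", 100)
  b <- paste0("TTTT", strrep("A", 96))
  seqs <- stats::setNames(c(a, a, b, b), c("a1", "a2", "b1", "b2"))
  part <- pop_partition(stats::setNames(c("A", "A", "B", "B"), names(seqs)))
  dx <- pairwise_dxy(dna_alignment(seqs), part)
  expect_equal(dx$dxy["A", "B"], 4)
  expect_equal(dx$percent["A", "B"], 4)
  expect_equal(dx$dxy["A", "A"], 0)

  # duplicated group: between = within * (n-1)/n exactly (the between-group
  # mean includes each individual's zero-distance self pair)
  set.seed(30)
  grp <- rand_alignment(10, 80, n_var = 8)
  seqs2 <- stats::setNames(c(grp$sequences, grp$sequences),
                           c(paste0("x", 1:10), paste0("y", 1:10)))
  part2 <- pop_partition(stats::setNames(rep(c("X", "Y"), each = 10),
                                         names(seqs2)))
  dx2 <- pairwise_dxy(dna_alignment(seqs2), part2)
  expect_equal(dx2$dxy["X", "Y"], dx2$dxy["X", "X"] * 9 / 10,
               tolerance = 1e-12)
  expect_equal(dx2$dxy["X", "X"], dx2$dxy["Y", "Y"], tolerance = 1e-12)

  # singleton group within-value is undefined
  seqs3 <- stats::setNames(c(a, a, b), c("p1", "p2", "q1"))
  part3 <- pop_partition(stats::setNames(c("P", "P", "Q"), names(seqs3)))
  dx3 <- pairwise_dxy(dna_alignment(seqs3), part3)
  expect_true(is.na(dx3$dxy["Q", "Q"]))
})

test_that("two-clade data show larger between- than within-clade Dxy", {
  set.seed(9)
  cfg <- sim_config(n_demes = 2, deme_sizes = c(80, 80),
                    sample_sizes = c(25, 25), sites_per_deme = c(3, 3),
                    burn_in = 150, migration = 0.001, seed = 99)
  sim <- simulate_dataset(cfg)
  part <- pop_partition(stats::setNames(
    as.character(sim$partition[sim$alignment$samples]),
    sim$alignment$samples))
  dx <- pairwise_dxy(sim$alignment, part)
  expect_gt(dx$dxy["demeA", "demeB"],
            max(dx$dxy["demeA", "demeA"], dx$dxy["demeB", "demeB"]))
})

test_that("haplotype networks keep ties and flag beyond-limit edges", {
  # two haplotypes one step apart
  part <- function(n) pop_partition(
    stats::setNames(rep("g", n), sprintf("s%d", 1:n)))
  tab <- collapse_haplotypes(dna_alignment(
    stats::setNames(c("AAAA", "AAAT"), c("s1", "s2"))), part(2))
  net <- build_haplotype_network(tab)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 1)

  # star: ancestor plus 3 singletons each one step away in different sites
  seqs <- c("AAAA", "TAAA", "ATAA", "AATA")
  tab2 <- collapse_haplotypes(dna_alignment(
    stats::setNames(seqs, sprintf("s%d", 1:4))), part(4))
  net2 <- build_haplotype_network(tab2)
  hub_edges <- net2$edges[net2$edges$from == "H01" | net2$edges$to == "H01", ]
  expect_equal(nrow(hub_edges), 3)
  expect_true(all(hub_edges$steps == 1))

  # two clades separated by >= 15 steps on a short alignment get flagged
  base <- strrep("A", 60)
  far <- paste0(strrep("T", 16), strrep("A", 44))
  seqs3 <- stats::setNames(c(base, sub("^A", "C", base), far,
                             sub("A$", "G", far)),
                           sprintf("s%d", 1:4))
  tab3 <- collapse_haplotypes(dna_alignment(seqs3), part(4))
  net3 <- build_haplotype_network(tab3)
  expect_true(any(net3$edges$beyond_limit))
  expect_true(all(net3$edges$steps[net3$edges$beyond_limit] > net3$limit))
  # graph is connected: n-1 or more edges
  expect_gte(nrow(net3$edges), 3)
})

test_that("network exports write GraphML and edge lists", {
  tab <- collapse_haplotypes(
    dna_alignment(stats::setNames(c("AAAA", "AAAT", "AATT"),
                                  c("s1", "s2", "s3"))),
    pop_partition(stats::setNames(rep("g", 3), c("s1", "s2", "s3"))))
  net <- build_haplotype_network(tab)
  g1 <- withr::local_tempfile(fileext = ".graphml")
  g2 <- withr::local_tempfile(fileext = ".tsv")
  export_haplotype_network(net, g1, g2)
  expect_true(file.size(g1) > 0)
  back <- utils::read.delim(g2)
  expect_equal(nrow(back), nrow(net$edges))
})
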