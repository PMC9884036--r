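#' Configuration for the forward-time island-model simulator
#'
#' Defaults emulate a four-island archipelago study: four demes sampled at
#' (131, 102, 49, 16) individuals, 18 dinucleotide microsatellite loci
#' under a two-phase mutation model, a 657-bp maternally inherited
#' sequence marker seeded with two divergent founder clades, a 60:40
#' male:female sample sex ratio, and collection sites spanning roughly
#' 500 km. Migration defaults give Nm of about 3 per pair, placing
#' equilibrium pairwise Fst in the 0.05-0.10 band.
#'
#' @param n_demes number of demes.
#' @param deme_sizes diploid census size per deme (all >= 2).
#' @param migration either a per-pair rate (scalar, applied to every
#'   ordered pair) or an `n_demes x n_demes` matrix of per-generation
#'   probabilities that an individual recorded in deme i was born in deme
#'   j (individual natal dispersal); off-diagonal rows must sum to <= 1.
#' @param sex_migration_multiplier male migration rate divided by female
#'   rate; parent-specific rates are scaled so their mean equals
#'   `migration`.
#' @param n_msat_loci number of microsatellite loci.
#' @param msat_mu per-copy per-generation microsatellite mutation rate.
#' @param p_multistep,mean_step two-phase mutation parameters.
#' @param motif_length repeat-unit length in bp (recycled over loci).
#' @param init_alleles number of equally frequent ladder alleles at
#'   initialization (`init = "ladder"`).
#' @param init `"ladder"` (equal-frequency allele ladder) or
#'   `"coalescent"` (equilibrium allele-size distribution drawn by
#'   coalescent simulation at `init_theta`).
#' @param init_theta scaled mutation rate for coalescent initialization
#'   (default 4 N_total msat_mu).
#' @param mt_length sequence length (bp) of the maternal marker.
#' @param mt_rate per-site per-generation mutation rate of the maternal
#'   marker.
#' @param mt_clade_divergence substitutions separating the two founder
#'   clades.
#' @param bottleneck `NULL`, or `list(deme =, start =, new_size =,
#'   duration =)`: deme index, generations before the end of the run at
#'   which the crash starts, crashed size, and crash length (the deme
#'   recovers afterwards).
#' @param burn_in generations before sampling; default 10 x max deme size.
#' @param sample_sizes individuals sampled per deme at the final
#'   generation.
#' @param sample_male_fraction fraction of males aimed for in each deme
#'   sample (default 0.6).
#' @param sites_per_deme collection sites per deme.
#' @param site_assortment probability an offspring inherits its mother's
#'   site rather than a random site of its deme (within-deme spatial
#'   signal; 0 = none).
#' @param deme_centers data frame (lat, lon) of deme centroids; defaults
#'   span ~500 km.
#' @param site_jitter_deg uniform jitter of site coordinates around the
#'   deme centroid, in degrees.
#' @param years calendar-year range sampled uniformly for collection year.
#' @param seed mandatory integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_demes = 4,
                       deme_sizes = c(250, 250, 250, 250),
                       migration = 0.004,
                       sex_migration_multiplier = 1,
                       n_msat_loci = 18,
                       msat_mu = 1e-3,
                       p_multistep = 0.2,
                       mean_step = 3.5,
                       motif_length = 2L,
                       init_alleles = 8,
                       init = c("ladder", "coalescent"),
                       init_theta = NULL,
                       mt_length = 657,
                       mt_rate = 2e-6,
                       mt_clade_divergence = 18,
                       bottleneck = NULL,
                       burn_in = NULL,
                       sample_sizes = c(131, 102, 49, 16),
                       sample_male_fraction = 0.6,
                       sites_per_deme = c(27, 21, 5, 6),
                       site_assortment = 0.5,
                       deme_centers = NULL,
                       site_jitter_deg = 0.15,
                       years = c(2009, 2020),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  init <- match.arg(init)
  if (length(deme_sizes) != n_demes) stop("deme_sizes length != n_demes")
  if (any(deme_sizes < 2)) stop("all deme sizes must be >= 2")
  if (length(sample_sizes) != n_demes) stop("sample_sizes length != n_demes")
  if (any(sample_sizes > deme_sizes))
    stop("sample sizes cannot exceed deme sizes")
  if (is.matrix(migration)) {
    M <- migration
  } else {
    M <- matrix(migration, n_demes, n_demes)
    diag(M) <- 0
  }
  if (any(rowSums(M) - diag(M) > 1)) stop("migration rows sum > 1")
  if (is.null(burn_in)) burn_in <- 10 * max(deme_sizes)
  if (is.null(init_theta)) init_theta <- 4 * sum(deme_sizes) * msat_mu
  if (is.null(deme_centers))
    deme_centers <- data.frame(
      lat = c(19.6, 20.8, 21.5, 22.1)[seq_len(n_demes)],
      lon = c(-155.5, -156.3, -158.0, -159.5)[seq_len(n_demes)])
  structure(list(
    n_demes = n_demes, deme_sizes = deme_sizes, migration = M,
    sex_migration_multiplier = sex_migration_multiplier,
    n_msat_loci = n_msat_loci, msat_mu = msat_mu,
    p_multistep = p_multistep, mean_step = mean_step,
    motif_length = rep(as.integer(motif_length),
                       length.out = n_msat_loci),
    init_alleles = init_alleles, init = init, init_theta = init_theta,
    mt_length = mt_length, mt_rate = mt_rate,
    mt_clade_divergence = mt_clade_divergence,
    bottleneck = bottleneck, burn_in = burn_in,
    sample_sizes = sample_sizes,
    sample_male_fraction = sample_male_fraction,
    sites_per_deme = rep(sites_per_deme, length.out = n_demes),
    site_assortment = site_assortment, deme_centers = deme_centers,
    site_jitter_deg = site_jitter_deg, years = years, seed = seed),
    class = "sim_config")
}

# draw a two-phase mutation step vector of length n
tpm_steps <- function(n, p_multistep, mean_step) {
  step <- rep(1L, n)
  multi <- stats::runif(n) < p_multistep
  if (any(multi))
    step[multi] <- 2L + stats::rgeom(sum(multi), 1 / (mean_step - 1))
  step * sample(c(-1L, 1L), n, replace = TRUE)
}

# equilibrium allele sizes for 2N gene copies by coalescent simulation
coalescent_init_sizes <- function(n_genes, theta, p_multistep, mean_step) {
  sizes <- integer(n_genes)
  members <- as.list(seq_len(n_genes))
  k <- n_genes
  while (k > 1) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    nmut <- stats::rpois(k, theta / 2 * t_k)
    for (ln in which(nmut > 0)) {
      st <- tpm_steps(nmut[ln], p_multistep, mean_step)
      sizes[members[[ln]]] <- sizes[members[[ln]]] + sum(st)
    }
    pair <- sample.int(k, 2)
    members[[pair[1]]] <- c(members[[pair[1]]], members[[pair[2]]])
    members[[pair[2]]] <- NULL
    k <- k - 1
  }
  sizes
}

mutate_sequence <- function(seq_chars, n_sites = 1) {
  pos <- sample.int(length(seq_chars), n_sites)
  for (p in pos)
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1)
  seq_chars
}

#' Island-model equilibrium Fst expectation
#'
#' Finite-island approximation Fst = 1 / (1 + 4 Ne m_total) per deme pair,
#' using each pair's mean deme size and the total emigration rate.
#' Asymmetric migration matrices are flagged (the approximation assumes
#' symmetric exchange).
#'
#' @param cfg a `sim_config`.
#' @return matrix of expected pairwise Fst; attribute `approximate` is TRUE
#'   when migration is asymmetric; m = 0 pairs report 1 (upper bound).
#' @export
expected_fst_truth <- function(cfg) {
  M <- cfg$migration
  K <- cfg$n_demes
  out <- matrix(0, K, K)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    m_tot <- sum(M[a, -a])
    N <- mean(cfg$deme_sizes[c(a, b)])
    out[a, b] <- out[b, a] <- if (m_tot == 0) 1 else 1 / (1 + 4 * N * m_tot)
  }
  attr(out, "approximate") <- !isSymmetric(M)
  out
}

#' Forward-time island-model simulation of a dual-marker dataset
#'
#' Discrete-generation Wright-Fisher reproduction within each deme with
#' balanced sexes and individual natal dispersal: each offspring is
#' assigned a sex, then migrates from its birth deme with the sex-specific
#' probability, carrying its full natal genotype (both parents are drawn
#' from the birth deme). Microsatellites mutate per meiosis under the
#' two-phase model; the maternal sequence marker is transmitted from the
#' mother with per-site mutations. Two divergent founder clades seed the maternal marker.
#' Samples are drawn at the final generation with the configured sex
#' ratio and assigned to jittered collection sites with within-deme
#' spatial assortment. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @return list of class `sim_dataset`: `genotypes` (`genotype_matrix`),
#'   `alignment` (`dna_alignment`), `metadata` (`sample_metadata`),
#'   `partition` (`pop_partition` by deme), `truth` (expected Fst matrix,
#'   realized migrant counts, true deme sizes, config).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rng_state <- if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
  set.seed(cfg$seed)
  K <- cfg$n_demes
  L <- cfg$n_msat_loci
  mult <- cfg$sex_migration_multiplier
  Mf <- cfg$migration * 2 / (1 + mult)
  Mm <- cfg$migration * 2 * mult / (1 + mult)

  # ladder base sizes per locus (bp), motif-aligned
  base_size <- 100L + cfg$motif_length *
    sample.int(60L, L, replace = TRUE)

  Ntot <- sum(cfg$deme_sizes)
  deme <- rep(seq_len(K), cfg$deme_sizes)
  # balanced sexes per deme
  sex <- unlist(lapply(cfg$deme_sizes, function(n) {
    s <- rep(c("F", "M"), length.out = n)
    sample(s)
  }))
  # microsatellite state
  A <- array(NA_integer_, c(Ntot, L, 2))
  for (l in seq_len(L)) {
    if (cfg$init == "ladder") {
      ladder <- base_size[l] + cfg$motif_length[l] *
        (seq_len(cfg$init_alleles) - 1L)
      A[, l, 1] <- sample(ladder, Ntot, replace = TRUE)
      A[, l, 2] <- sample(ladder, Ntot, replace = TRUE)
    } else {
      sz <- coalescent_init_sizes(2 * Ntot, cfg$init_theta,
                                  cfg$p_multistep, cfg$mean_step)
      sz <- base_size[l] + cfg$motif_length[l] * (sz - min(sz))
      sz <- sample(sz)
      A[, l, 1] <- sz[seq_len(Ntot)]
      A[, l, 2] <- sz[Ntot + seq_len(Ntot)]
    }
  }
  # maternal marker: haplotype pool
  founder <- sample(c("A", "C", "G", "T"), cfg$mt_length, replace = TRUE)
  clade2 <- mutate_sequence(founder, cfg$mt_clade_divergence)
  pool <- list(founder, clade2)
  # clade assignment: deme 1 -> clade 1, deme 2 -> clade 2, rest mixed
  clade_p <- rep(0.5, K)
  if (K >= 1) clade_p[1] <- 0.02
  if (K >= 2) clade_p[2] <- 0.98
  mt <- ifelse(stats::runif(Ntot) < clade_p[deme], 2L, 1L)
  # sites
  n_sites <- cfg$sites_per_deme
  site_tab <- do.call(rbind, lapply(seq_len(K), function(d) {
    data.frame(
      deme = d,
      site_id = sprintf("S%d_%02d", d, seq_len(n_sites[d])),
      lat = cfg$deme_centers$lat[d] +
        stats::runif(n_sites[d], -cfg$site_jitter_deg, cfg$site_jitter_deg),
      lon = cfg$deme_centers$lon[d] +
        stats::runif(n_sites[d], -cfg$site_jitter_deg, cfg$site_jitter_deg))
  }))
  site <- vapply(deme, function(d)
    sample(site_tab$site_id[site_tab$deme == d], 1), "")

  bn <- cfg$bottleneck
  total_gens <- cfg$burn_in
  migrant_log <- integer(total_gens)

  sizes_now <- cfg$deme_sizes
  for (gen in seq_len(total_gens)) {
    gens_left <- total_gens - gen
    sizes_next <- cfg$deme_sizes
    if (!is.null(bn) && gens_left < bn$start && gens_left >= bn$start - bn$duration)
      sizes_next[bn$deme] <- bn$new_size
    if (any(sizes_next < 2)) stop("deme extinction under bottleneck")
    Nn <- sum(sizes_next)
    deme_new <- rep(seq_len(K), sizes_next)
    # balanced sexes, assigned before migration so that each individual's
    # own sex governs its dispersal probability
    sex_new <- unlist(lapply(sizes_next, function(n)
      sample(rep(c("F", "M"), length.out = n))))
    # individual migration: each offspring occupying a slot in deme i was
    # born in deme j (both parents drawn from j) with the sex-specific
    # per-generation probability; migrants carry their full natal genotype
    birth <- deme_new
    u <- stats::runif(Nn)
    cum_f <- matrix(t(apply(Mf, 1, cumsum)), K)
    cum_m <- matrix(t(apply(Mm, 1, cumsum)), K)
    for (d in seq_len(K)) {
      for (sx in c("F", "M")) {
        i <- which(deme_new == d & sex_new == sx)
        cc <- c(0, if (sx == "F") cum_f[d, ] else cum_m[d, ])
        for (j in seq_len(K)) {
          sel <- i[u[i] >= cc[j] & u[i] < cc[j + 1]]
          birth[sel] <- j
        }
      }
    }
    migrant_log[gen] <- sum(birth != deme_new)
    # parents: both drawn from the birth deme of the current generation
    fem <- lapply(seq_len(K), function(d) which(deme == d & sex == "F"))
    mal <- lapply(seq_len(K), function(d) which(deme == d & sex == "M"))
    mother <- integer(Nn); father <- integer(Nn)
    for (d in seq_len(K)) {
      i <- which(birth == d)
      if (length(i)) {
        mother[i] <- fem[[d]][sample.int(length(fem[[d]]), length(i),
                                         replace = TRUE)]
        father[i] <- mal[[d]][sample.int(length(mal[[d]]), length(i),
                                         replace = TRUE)]
      }
    }
    # gametes
    A_new <- array(NA_integer_, c(Nn, L, 2))
    chm <- matrix(sample.int(2L, Nn * L, replace = TRUE), Nn, L)
    chf <- matrix(sample.int(2L, Nn * L, replace = TRUE), Nn, L)
    li <- rep(seq_len(L), each = Nn)
    A_new[, , 1] <- A[cbind(rep(mother, L), li, as.vector(chm))]
    A_new[, , 2] <- A[cbind(rep(father, L), li, as.vector(chf))]
    # mutation
    for (copy in 1:2) {
      mut <- which(stats::runif(Nn * L) < cfg$msat_mu)
      if (length(mut)) {
        st <- tpm_steps(length(mut), cfg$p_multistep, cfg$mean_step)
        flat <- A_new[, , copy]
        flat[mut] <- flat[mut] +
          st * rep(cfg$motif_length, each = Nn)[mut]
        A_new[, , copy] <- flat
      }
    }
    # maternal marker
    mt_new <- mt[mother]
    pm <- 1 - (1 - cfg$mt_rate)^cfg$mt_length
    hit <- which(stats::runif(Nn) < pm)
    for (i in hit) {
      newseq <- mutate_sequence(pool[[mt_new[i]]], 1)
      pool[[length(pool) + 1]] <- newseq
      mt_new[i] <- length(pool)
    }
    # sites: non-migrants inherit their mother's site with assortment;
    # migrants land on a random site of the destination deme
    site_new <- character(Nn)
    keep <- birth == deme_new & stats::runif(Nn) < cfg$site_assortment
    site_new[keep] <- site[mother[keep]]
    for (d in seq_len(K)) {
      i <- which(!keep & deme_new == d)
      if (length(i))
        site_new[i] <- sample(site_tab$site_id[site_tab$deme == d],
                              length(i), replace = TRUE)
    }
    A <- A_new; mt <- mt_new; deme <- deme_new
    sex <- sex_new; site <- site_new
    sizes_now <- sizes_next
  }

  # sampling
  take <- integer(0)
  for (d in seq_len(K)) {
    n_d <- cfg$sample_sizes[d]
    n_m <- round(n_d * cfg$sample_male_fraction)
    all_d <- which(deme == d)
    if (length(all_d) < n_d)
      stop("deme ", d, " holds ", length(all_d), " individuals < sample size ",
           n_d)
    males <- which(deme == d & sex == "M")
    females <- which(deme == d & sex == "F")
    n_m <- min(n_m, length(males))
    n_f <- min(n_d - n_m, length(females))
    sel <- c(males[sample.int(length(males), n_m)],
             females[sample.int(length(females), n_f)])
    if (length(sel) < n_d) {
      extra <- setdiff(all_d, sel)
      sel <- c(sel, extra[sample.int(length(extra), n_d - length(sel))])
    }
    take <- c(take, sort(sel))
  }
  ids <- sprintf("%s%03d", LETTERS[deme[take]], seq_along(take))
  gm <- genotype_matrix(A[take, , , drop = FALSE], ids,
                        sprintf("loc%02d", seq_len(L)), cfg$motif_length)
  seqs <- vapply(mt[take], function(h) paste(pool[[h]], collapse = ""), "")
  aln <- dna_alignment(stats::setNames(seqs, ids))
  site_row <- match(site[take], site_tab$site_id)
  meta <- sample_metadata(data.frame(
    sample_id = ids,
    deme = paste0("deme", LETTERS[deme[take]]),
    site_id = site[take],
    lat = site_tab$lat[site_row], lon = site_tab$lon[site_row],
    sex = sex[take],
    year = sample(seq(cfg$years[1], cfg$years[2]), length(take),
                  replace = TRUE),
    source = "simulated", stringsAsFactors = FALSE))
  part <- partition_from_metadata(meta)
  truth <- list(expected_fst = expected_fst_truth(cfg),
                migrants_per_generation = migrant_log,
                true_ne = cfg$deme_sizes,
                bottleneck = cfg$bottleneck,
                config = cfg)
  structure(list(genotypes = gm, alignment = aln, metadata = meta,
                 partition = part, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d samples, %d demes, %d msat loci, %d bp maternal marker\n",
    length(x$genotypes$samples), x$truth$config$n_demes,
    length(x$genotypes$loci), x$alignment$length_bp))
  invisible(x)
}

#' Write a simulated dataset to standard files
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return invisible named vector of paths (genepop, fasta, metadata,
#'   truth JSON).
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genepop = file.path(dir, "genotypes.gen"),
             fasta = file.path(dir, "mtdna.fasta"),
             metadata = file.path(dir, "metadata.csv"),
             truth = file.path(dir, "truth.json"))
  write_genepop(sim$genotypes, sim$partition, paths["genepop"])
  write_fasta_alignment(sim$alignment, paths["fasta"])
  write_sample_metadata(sim$metadata, paths["metadata"])
  tr <- sim$truth
  tr$config <- unclass(tr$config)
  tr$config$deme_centers <- NULL
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}
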