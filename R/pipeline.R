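# write a report table as TSV with a '#' parameter header
write_report_tsv <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(params), unlist(params), sep = "=",
                                collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full dual-marker analysis pipeline
#'
#' Executes the analysis stages in dependency order on whatever inputs are
#' supplied - sequence diversity and neutrality (needs `aln`),
#' microsatellite diversity, structure, isolation by distance, sex-biased
#' dispersal, effective sizes and M-ratio (need `gm`) - and writes one TSV
#' per report table into `out_dir`. A stage whose inputs are absent is
#' recorded as skipped; a stage that errors is isolated and its message
#' logged. One master seed drives per-stage substreams, so identical
#' inputs + seed give an identical bundle.
#'
#' @param gm optional `genotype_matrix`.
#' @param aln optional `dna_alignment`.
#' @param meta optional `sample_metadata` (needed for site-level IBD and
#'   sex tests).
#' @param part `pop_partition`; defaults to deme from `meta`.
#' @param out_dir output directory.
#' @param seed master integer seed.
#' @param n_perm permutations for Fst/AMOVA/Mantel (default 999).
#' @param maf LD-Ne allele-frequency screen (default 0.05).
#' @param sex_n_rand sex-label randomizations for the dispersal stage
#'   (default 1000; frequency-based metrics capped at 200 draws).
#' @param rarefaction_g gene copies for rarefied richness (default 32).
#' @param theta_grid critical-M theta grid (default c(0.01, 0.1, 1, 10)).
#' @param critm_reps critical-M replicates (default 2000).
#' @param msat_mu_bracket microsatellite mutation rates for long-term Ne
#'   (default c(1e-3, 1e-5)).
#' @param mt_u_bracket per-sequence mutation rates for female Ne
#'   (default c(8.061e-6, 1.089e-4)).
#' @param exclude_ambiguous drop heteroplasmy-flagged sequences from the
#'   mtDNA stages (default TRUE).
#' @return list of class `report_bundle`: `tables` (named list of data
#'   frames), `skipped`, `errors`, `paths`, `seed`.
#' @export
run_pipeline <- function(gm = NULL, aln = NULL, meta = NULL, part = NULL,
                         out_dir, seed, n_perm = 999, maf = 0.05,
                         sex_n_rand = 1000,
                         rarefaction_g = 32,
                         theta_grid = c(0.01, 0.1, 1, 10),
                         critm_reps = 2000,
                         msat_mu_bracket = c(1e-3, 1e-5),
                         mt_u_bracket = c(8.061e-6, 1.089e-4),
                         exclude_ambiguous = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(part) && !is.null(meta)) part <- partition_from_metadata(meta)
  if (is.null(part)) stop("a partition (or metadata) is required")
  tables <- list()
  skipped <- character()
  errors <- character()
  paths <- character()
  run_stage <- function(name, need, fun) {
    if (!need) {
      skipped <<- c(skipped, name)
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      errors <<- c(errors, stats::setNames(conditionMessage(res), name))
    } else {
      tables[[name]] <<- res
      p <- file.path(out_dir, paste0(name, ".tsv"))
      write_report_tsv(res, p, list(stage = name, seed = seed,
                                    n_perm = n_perm))
      paths <<- c(paths, stats::setNames(p, name))
    }
    invisible(NULL)
  }
  aln_use <- aln
  if (!is.null(aln) && exclude_ambiguous) {
    scr <- screen_ambiguous_sequences(aln)
    aln_use <- scr$clean
  }
  mt_part <- if (!is.null(aln_use))
    pop_partition(stats::setNames(as.character(part[aln_use$samples]),
                                  aln_use$samples))

  run_stage("diversity_mt", !is.null(aln_use), function() {
    do.call(rbind, lapply(levels(mt_part), function(g) {
      sub <- aln_subset(aln_use, which(mt_part == g))
      s <- mt_diversity_summary(sub)
      data.frame(group = g, n = s$n, h = s$h, S = s$S, Hd = s$Hd,
                 Hd_sd = s$Hd_sd, pi_site = s$pi_site, pi_sd = s$pi_sd,
                 theta_site = s$theta_site, theta_seq = s$theta_seq,
                 length_used = s$length_used)
    }))
  })
  run_stage("neutrality", !is.null(aln_use), function() {
    do.call(rbind, lapply(levels(mt_part), function(g) {
      sub <- aln_subset(aln_use, which(mt_part == g))
      s <- mt_diversity_summary(sub)
      D <- if (s$n >= 4 && s$S >= 1) tajimas_d(s$n, s$S, s$pi_seq) else NA
      Fs <- if (s$h >= 2 && s$pi_seq > 0) fus_fs(s$n, s$h, s$pi_seq) else NA
      data.frame(group = g, n = s$n, S = s$S, tajima_d = as.numeric(D),
                 fu_fs = as.numeric(Fs))
    }))
  })
  run_stage("dxy", !is.null(aln_use) && nlevels(mt_part) >= 2, function() {
    dx <- pairwise_dxy(aln_use, mt_part)
    ut <- upper.tri(dx$dxy, diag = TRUE)
    data.frame(pair = unname(outer(rownames(dx$dxy), colnames(dx$dxy),
                                   paste)[ut]),
               dxy = unname(dx$dxy[ut]),
               percent = unname(dx$percent[ut]))
  })
  run_stage("haplotype_network", !is.null(aln_use), function() {
    tab <- collapse_haplotypes(aln_use, mt_part)
    if (length(tab$haplotypes) < 2)
      return(data.frame(from = character(), to = character(),
                        steps = integer(), beyond_limit = logical()))
    build_haplotype_network(tab)$edges
  })
  run_stage("diversity_msat", !is.null(gm), function() locus_summary(gm, part))
  run_stage("richness", !is.null(gm), function()
    rarefied_richness(gm, part, rarefaction_g))
  run_stage("fst_pairwise", !is.null(gm) && nlevels(part) >= 2, function() {
    fm <- pairwise_fst_matrix(gm, part, n_perm,
                              seed = stage_seed(seed, "fst_msat"))
    fe <- ena_corrected_fst(gm, part)
    ut <- upper.tri(fm$values)
    df <- data.frame(
      pair = outer(rownames(fm$values), colnames(fm$values), paste)[ut],
      fst = fm$values[ut], p = fm$p_values[ut], fst_ena = fe$values[ut])
    if (!is.null(aln_use) && nlevels(mt_part) >= 2) {
      fmt <- pairwise_fst_matrix(aln_use, mt_part, n_perm,
                                 seed = stage_seed(seed, "fst_mt"))
      mt_df <- data.frame(
        pair = outer(rownames(fmt$values), colnames(fmt$values), paste)[
          upper.tri(fmt$values)],
        phist = fmt$values[upper.tri(fmt$values)],
        phist_p = fmt$p_values[upper.tri(fmt$values)])
      df <- merge(df, mt_df, by = "pair", all = TRUE)
    }
    df
  })
  run_stage("amova", !is.null(gm) && nlevels(part) >= 2, function() {
    am <- amova(gm, part, n_perm, seed = stage_seed(seed, "amova"))
    data.frame(marker = "microsatellite", am$components,
               p_phi_st = unname(am$p_values["Phi_ST"]), row.names = NULL)
  })
  run_stage("amova_mt", !is.null(aln_use) && nlevels(mt_part) >= 2,
            function() {
    am <- amova(aln_use, mt_part, n_perm, seed = stage_seed(seed, "amovamt"))
    data.frame(marker = "mtDNA", am$components,
               p_phi_st = unname(am$p_values["Phi_ST"]), row.names = NULL)
  })
  run_stage("ordination", !is.null(gm), function() {
    pca <- run_pca(gm)
    dapc <- if (nlevels(part) >= 2) run_dapc(gm, part) else NULL
    df <- data.frame(sample_id = rownames(pca$scores),
                     group = as.character(part[rownames(pca$scores)]),
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2])
    if (!is.null(dapc)) {
      df$LD1 <- dapc$scores[df$sample_id, 1]
      if (ncol(dapc$scores) >= 2) df$LD2 <- dapc$scores[df$sample_id, 2]
    }
    df
  })
  run_stage("ibd", !is.null(gm) && !is.null(meta) &&
              all(c("site_id", "lat", "lon") %in% names(meta)), function() {
    res <- site_ibd_mantel(gm, meta, n_perm = n_perm,
                           seed = stage_seed(seed, "ibd"))
    data.frame(mantel_r = res$mantel_r, mantel_p = res$mantel_p,
               n_sites = res$n_sites)
  })
  run_stage("sex_bias", !is.null(gm) && !is.null(meta) &&
              "sex" %in% names(meta), function() {
    sx <- stats::setNames(meta$sex, meta$sample_id)
    res <- sex_bias_test_suite(gm, part, sx, n_rand = sex_n_rand,
                               n_rand_heavy = min(sex_n_rand, 200),
                               seed = stage_seed(seed, "sexbias"))
    data.frame(metric = rownames(res$table), female = res$table[, "F"],
               male = res$table[, "M"],
               p_one_sided = res$p_one_sided[rownames(res$table)])
  })
  run_stage("ne_contemporary", !is.null(gm), function() {
    do.call(rbind, lapply(levels(part), function(g) {
      est <- tryCatch(ld_ne_estimate(gm, part, g, maf),
                      error = function(e) NULL)
      if (is.null(est)) return(NULL)
      fmt <- function(v) ifelse(is.finite(v), sprintf("%.1f", v), "inf")
      data.frame(group = g, ne = fmt(est$ne),
                 jk_lo = fmt(est$ci_jackknife[1]),
                 jk_hi = fmt(est$ci_jackknife[2]),
                 par_lo = fmt(est$ci_parametric[1]),
                 par_hi = fmt(est$ci_parametric[2]),
                 S = est$S, n_pairs = est$n_pairs)
    }))
  })
  run_stage("ne_longterm", !is.null(gm), function() {
    ls <- locus_summary(gm, part)
    do.call(rbind, lapply(levels(part), function(g) {
      H <- mean(ls$He[ls$group == g], na.rm = TRUE)
      ne <- longterm_ne_het(H, msat_mu_bracket)
      data.frame(group = g, H = H, ne, row.names = NULL)
    }))
  })
  run_stage("ne_female_mt", !is.null(aln_use), function() {
    do.call(rbind, lapply(levels(mt_part), function(g) {
      sub <- aln_subset(aln_use, which(mt_part == g))
      if (length(sub$samples) < 2) return(NULL)
      s <- mt_diversity_summary(sub)
      data.frame(group = g, theta_seq = s$theta_seq,
                 female_ne_from_theta(s$theta_seq, mt_u_bracket),
                 row.names = NULL)
    }))
  })
  run_stage("m_ratio", !is.null(gm), function() {
    do.call(rbind, lapply(levels(part), function(g) {
      mr <- m_ratio(gm, part, g)
      data.frame(group = g, mean_M = mr$mean, sd_M = mr$sd,
                 n_loci = mr$n_loci)
    }))
  })
  run_stage("critical_m", !is.null(gm), function() {
    g_sizes <- 2 * as.integer(table(part))
    set.seed(stage_seed(seed, "critm"))
    cbind(n_genes = min(g_sizes),
          critical_m(min(g_sizes), length(gm$loci), theta_grid,
                     reps = critm_reps,
                     seed = stage_seed(seed, "critm")))
  })
  log_df <- data.frame(
    stage = c(names(paths), skipped, names(errors)),
    status = c(rep("ok", length(paths)), rep("skipped", length(skipped)),
               rep("error", length(errors))),
    detail = c(unname(paths), rep("missing inputs", length(skipped)),
               unname(errors)))
  write_report_tsv(log_df, file.path(out_dir, "run_log.tsv"),
                   list(seed = seed))
  structure(list(tables = tables, skipped = skipped, errors = errors,
                 paths = paths, seed = seed, out_dir = out_dir),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle: %d tables written to %s (seed %d)\n",
              length(x$tables), x$out_dir, x$seed))
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  if (length(x$errors))
    cat("errors:", paste(names(x$errors), x$errors, sep = ": ",
                         collapse = "; "), "\n")
  invisible(x)
}

#' Rarefied sequence-diversity tiers
#'
#' Random subsampling without replacement of each group to each target
#' size (groups smaller than a tier are skipped for it), re-running the
#' sequence diversity summary per tier - the standard equal-sample-size
#' re-analysis for uneven sampling.
#'
#' @param aln a `dna_alignment`.
#' @param part a `pop_partition`.
#' @param sizes integer vector of tier sizes.
#' @param seed integer seed.
#' @return data frame: tier size, group, and the diversity summary
#'   columns; a `skipped` attribute lists group/size pairs skipped.
#' @export
subsample_rarefied_run <- function(aln, part, sizes, seed = 1L) {
  part <- part_align(part, aln$samples)
  out <- list()
  skipped <- character()
  for (sz in sizes) {
    for (g in levels(part)) {
      idx <- which(part == g)
      if (length(idx) < sz) {
        skipped <- c(skipped, paste0(g, "@", sz))
        next
      }
      set.seed(stage_seed(seed, paste0("rar", g, sz)))
      sub <- aln_subset(aln, sample(idx, sz))
      s <- mt_diversity_summary(sub)
      out[[length(out) + 1]] <- data.frame(
        size = sz, group = g, n = s$n, h = s$h, S = s$S, Hd = s$Hd,
        pi_site = s$pi_site, theta_seq = s$theta_seq)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}
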