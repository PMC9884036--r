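#!/usr/bin/env Rscript
# Stage 6: demographic history - bottleneck and expansion signals.
#
# Per island: the modified Garza-Williamson M-ratio against simulated
# critical values Mc over a theta grid spanning the mitochondrial
# estimates (two-phase mutation model, p_multistep 0.2, mean step 3.5),
# and the sequence neutrality tests (Tajima's D, Fu's Fs).

suppressMessages(library(archipop))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

if (!file.exists("results/data/genotypes.gen"))
  stop("no simulated dataset found: run analysis/01_simulate.R first")

gp <- read_genepop("results/data/genotypes.gen")
aln <- screen_ambiguous_sequences(
  read_fasta_alignment("results/data/mtdna.fasta"))$clean
meta <- read_sample_metadata("results/data/metadata.csv")
gm <- gp$genotypes
part <- partition_from_metadata(meta)
mt_part <- pop_partition(stats::setNames(
  as.character(part[aln$samples]), aln$samples))

theta_grid <- c(0.01, 0.1, 1, 10)
rows <- list()
for (g in levels(part)) {
  mr <- m_ratio(gm, part, g)
  n_genes <- 2 * sum(part == g)
  mc <- critical_m(n_genes, length(gm$loci), theta_grid, reps = 2000,
                   seed = stage_seed(seed, paste0("critm", g)))
  cat(sprintf("%s: M = %.2f +/- %.2f, Mc range [%.2f-%.2f]%s\n",
              g, mr$mean, mr$sd, min(mc$Mc), max(mc$Mc),
              if (mr$mean < min(mc$Mc)) "  <- below critical range" else ""))
  rows[[g]] <- data.frame(group = g, mean_M = mr$mean, sd_M = mr$sd,
                          n_loci = mr$n_loci, Mc_min = min(mc$Mc),
                          Mc_max = max(mc$Mc))
}
dir.create("results", showWarnings = FALSE)
utils::write.table(do.call(rbind, rows), "results/m_ratio.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

neut <- do.call(rbind, lapply(levels(mt_part), function(g) {
  s <- mt_diversity_summary(aln_subset(aln, which(mt_part == g)))
  D <- if (s$n >= 4 && s$S >= 1) tajimas_d(s$n, s$S, s$pi_seq) else NA
  Fs <- if (s$h >= 2 && s$pi_seq > 0) fus_fs(s$n, s$h, s$pi_seq) else NA
  data.frame(group = g, n = s$n, S = s$S,
             tajima_d = round(as.numeric(D), 3),
             fu_fs = round(as.numeric(Fs), 3))
}))
cat("neutrality tests:\n")
print(neut)
utils::write.table(neut, "results/neutrality.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/m_ratio.tsv, results/neutrality.tsv\n")
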