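#!/usr/bin/env Rscript
# Stage 3: population structure and isolation by distance.
#
# Pairwise Fst for both markers (with the ENA null-allele correction for
# microsatellites), AMOVA, PCA/DAPC ordination scores, and the two IBD
# tests (site-level Mantel on chord distances; Fst/(1-Fst) vs ln km
# regression between islands).

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

wc <- wc_f_statistics(gm, part, seed = stage_seed(seed, "wc"))
cat("global F-statistics (95% bootstrap CI over loci):\n")
for (s in names(wc$estimates))
  cat(sprintf("  %s = %.3f [%.3f, %.3f]\n", s, wc$estimates[s],
              wc$ci[1, s], wc$ci[2, s]))

fm <- pairwise_fst_matrix(gm, part, n_perm = 999,
                          seed = stage_seed(seed, "fst"))
fe <- ena_corrected_fst(gm, part)
fmt <- pairwise_fst_matrix(aln, mt_part, n_perm = 999,
                           seed = stage_seed(seed, "phist"))
cat("microsatellite pairwise Fst (ENA-corrected in brackets):\n")
print(round(fm$values, 3))
print(round(fe$values, 3))
cat("mitochondrial pairwise PhiST:\n")
print(round(fmt$values, 3))

am <- amova(gm, part, n_perm = 999, seed = stage_seed(seed, "amova"))
am_mt <- amova(aln, mt_part, n_perm = 999, seed = stage_seed(seed, "amovamt"))
cat("AMOVA, microsatellites:\n"); print(am)
cat("AMOVA, mtDNA:\n"); print(am_mt)

pca <- run_pca(gm)
dapc <- run_dapc(gm, part)
cat(sprintf("PCA axis 1/2: %.2f%% / %.2f%% of variance; DAPC retained %d PCs\n",
            pca$percent_variance[1], pca$percent_variance[2], dapc$n_pcs))

ibd <- site_ibd_mantel(gm, meta, n_perm = 999,
                       seed = stage_seed(seed, "mantel"))
cat(sprintf("site-level IBD Mantel: r = %.3f, p = %.3g over %d sites\n",
            ibd$mantel_r, ibd$mantel_p, ibd$n_sites))

centers <- stats::aggregate(cbind(lat, lon) ~ deme, data = meta, FUN = mean)
km <- site_distance_matrix(data.frame(site_id = centers$deme,
                                      lat = centers$lat, lon = centers$lon))
km <- km[levels(part), levels(part)]
reg <- ibd_regression(fm, km, gm = gm, part = part,
                      seed = stage_seed(seed, "ibdreg"))
cat(sprintf("island-level IBD slope b = %.4f (95%% CI %.4f-%.4f)\n",
            reg$slope, reg$ci[1], reg$ci[2]))

dir.create("results", showWarnings = FALSE)
ut <- upper.tri(fm$values)
utils::write.table(
  data.frame(pair = outer(rownames(fm$values), colnames(fm$values),
                          paste, sep = "-")[ut],
             fst = fm$values[ut], fst_p = fm$p_values[ut],
             fst_ena = fe$values[ut],
             km = km[ut]),
  "results/fst_pairwise.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
scores <- data.frame(sample_id = rownames(pca$scores),
                     deme = as.character(part),
                     PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                     LD1 = dapc$scores[, 1])
utils::write.table(scores, "results/ordination.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/fst_pairwise.tsv, results/ordination.tsv\n")
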