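#!/usr/bin/env Rscript
# Stage 4: sex-biased dispersal tests on the nuclear marker.
#
# Runs the full per-sex suite (mAIc, vAIc, Fst, Fis, relatedness, Ho, Hs)
# with one-sided randomization p-values oriented toward male-biased
# dispersal, across islands.

suppressMessages(library(archipop))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

if (!file.exists("results/data/genotypes.gen"))
  stop("no simulated dataset found: run analysis/01_simulate.R first")

gp <- read_genepop("results/data/genotypes.gen")
meta <- read_sample_metadata("results/data/metadata.csv")
part <- partition_from_metadata(meta)
sx <- stats::setNames(meta$sex, meta$sample_id)

res <- sex_bias_test_suite(gp$genotypes, part, sx, dispersing_sex = "M",
                           n_rand = 10000, seed = stage_seed(seed, "sex"))
print(res)

tab <- data.frame(metric = rownames(res$table),
                  female = round(res$table[, "F"], 4),
                  male = round(res$table[, "M"], 4),
                  p_one_sided = round(res$p_one_sided[rownames(res$table)], 4))
dir.create("results", showWarnings = FALSE)
utils::write.table(tab, "results/sex_bias.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("wrote results/sex_bias.tsv\n")
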