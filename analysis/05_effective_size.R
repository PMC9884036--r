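#!/usr/bin/env Rscript
# Stage 5: contemporary and long-term effective population sizes.
#
# Per island: the single-sample LD estimate (MAF screen 0.05, random
# mating, jackknife + parametric CIs), long-term Ne from mean expected
# heterozygosity under SMM and IAM at bracketing mutation rates, and the
# long-term female Ne from mitochondrial Watterson's theta at the two
# literature substitution rates.

suppressMessages(library(archipop))

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
fmt_inf <- function(v) ifelse(is.finite(v), sprintf("%.0f", v), "inf")

rows <- list()
for (g in levels(part)) {
  est <- tryCatch(ld_ne_estimate(gm, part, g, maf = 0.05),
                  error = function(e) NULL)
  if (is.null(est)) next
  print(est)
  rows[[g]] <- data.frame(
    group = g, ne = fmt_inf(est$ne),
    jk_lo = fmt_inf(est$ci_jackknife[1]), jk_hi = fmt_inf(est$ci_jackknife[2]),
    par_lo = fmt_inf(est$ci_parametric[1]),
    par_hi = fmt_inf(est$ci_parametric[2]))
}
dir.create("results", showWarnings = FALSE)
utils::write.table(do.call(rbind, rows), "results/ne_contemporary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

ls <- locus_summary(gm, part)
lt <- do.call(rbind, lapply(levels(part), function(g) {
  H <- mean(ls$He[ls$group == g], na.rm = TRUE)
  data.frame(group = g, H = round(H, 3),
             longterm_ne_het(H, c(1e-3, 1e-5)), row.names = NULL)
}))
cat("long-term Ne from heterozygosity (SMM / IAM):\n")
print(lt)
utils::write.table(lt, "results/ne_longterm.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

nef <- do.call(rbind, lapply(levels(mt_part), function(g) {
  sub <- aln_subset(aln, which(mt_part == g))
  if (length(sub$samples) < 2) return(NULL)
  s <- mt_diversity_summary(sub)
  data.frame(group = g, theta_seq = round(s$theta_seq, 3),
             female_ne_from_theta(s$theta_seq, c(8.061e-6, 1.089e-4)),
             row.names = NULL)
}))
cat("long-term female Ne from mitochondrial theta:\n")
print(nef)
utils::write.table(nef, "results/ne_female_mt.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/ne_*.tsv\n")
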