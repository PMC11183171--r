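#!/usr/bin/env Rscript

# Permutation statistics relating communities, drivers, and functions:
# PERMANOVA and constrained PCoA of each kingdom's Bray-Curtis distances by
# slope position, Mantel screens of function distance against community
# distance and biotic-association distance, and variation partitioning of
# the bacterial composition between abiotic (position) and biotic
# (AM richness, PPA, PNA) predictor sets.

suppressPackageStartupMessages(library(rhizonet))

dat <- "results/data"; out <- "results"
seed <- 101
n_perm <- 999
tabs <- lapply(c(bacteria = "bacteria", rhizobia = "rhizobia",
                 am_fungi = "am_fungi"), function(k)
  read_abundance_tsv(file.path(dat, paste0("abundance_", k, ".tsv")),
                     file.path(dat, "metadata.tsv")))
meta <- tabs$bacteria$metadata
position <- setNames(meta$position, meta$sample_id)

rows <- list()
for (k in names(tabs)) {
  d <- bray_curtis(tabs[[k]])
  pm <- permanova(d, position, n_perm, seed = seed)
  cp <- constrained_pcoa(d, position, n_perm, seed = seed)
  rows[[length(rows) + 1]] <- data.frame(
    analysis = paste0("permanova_", k), statistic = pm$statistic,
    R2_or_fraction = pm$R2, p_value = pm$p_value)
  rows[[length(rows) + 1]] <- data.frame(
    analysis = paste0("cpcoa_", k), statistic = NA,
    R2_or_fraction = cp$constrained_fraction, p_value = cp$p_value)
  cat(sprintf("%-9s PERMANOVA F = %.2f (R2 %.2f, p %.3f); CPCoA %.1f%% (p %.3f)\n",
              k, pm$statistic, pm$R2, pm$p_value,
              100 * cp$constrained_fraction, cp$p_value))
}

fd <- read.delim(file.path(dat, "functions.tsv"), check.names = FALSE)
fn <- function_table(`rownames<-`(as.matrix(fd[, -1]), fd$sample_id))
dfun <- as.matrix(dist(z_standardize(fn)))
assoc <- read.delim(file.path(out, "biotic_associations.tsv"))
dppa <- as.matrix(dist(assoc$PPA_rpoB_AMF))
rownames(dppa) <- colnames(dppa) <- assoc$sample_id

for (x in list(c("function_vs_bacteria", "bacteria"),
               c("function_vs_am_fungi", "am_fungi"))) {
  mt <- mantel_test(dfun, bray_curtis(tabs[[x[2]]]), n_permutations = n_perm,
                    seed = seed)
  rows[[length(rows) + 1]] <- data.frame(
    analysis = paste0("mantel_", x[1]), statistic = mt$statistic,
    R2_or_fraction = NA, p_value = mt$p_value)
  cat(sprintf("Mantel %-22s r = %.3f, p = %.3f\n", x[1], mt$statistic,
              mt$p_value))
}
mt2 <- mantel_test(dfun, dppa, n_permutations = n_perm, seed = seed)
cat(sprintf("Mantel function_vs_PPA_rpoB_AMF r = %.3f, p = %.3f\n",
            mt2$statistic, mt2$p_value))

abiotic <- cbind(pos_score = as.integer(factor(position,
                                               c("top", "middle", "bottom"))))
biotic <- cbind(am_richness = rowSums(tabs$am_fungi$counts > 0),
                ppa = assoc$PPA_B_AMF, pna = assoc$PNA_B_AMF)
vp <- variation_partitioning(bray_curtis(tabs$bacteria), abiotic, biotic,
                             n_perm, seed = seed)
cat("Variation partitioning of bacterial composition (adjusted R2):\n")
print(round(vp$fractions, 3))
rows[[length(rows) + 1]] <- data.frame(
  analysis = "varpart_bacteria_biotic_unique", statistic = NA,
  R2_or_fraction = vp$fractions["unique_b"], p_value = vp$p_value)

res <- do.call(rbind, rows)
write.table(res, file.path(out, "stats_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "stats_results.tsv"), "\n")
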