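#!/usr/bin/env Rscript

# Multifunctionality facets from the 12-function table: per-function
# z-scores, the averaging index, and three principal axes, summarized by
# slope position.

suppressPackageStartupMessages(library(rhizonet))

dat <- "results/data"; out <- "results"
fd <- read.delim(file.path(dat, "functions.tsv"), check.names = FALSE)
fn <- function_table(`rownames<-`(as.matrix(fd[, -1]), fd$sample_id))
meta <- read.delim(file.path(dat, "metadata.tsv"))

mf <- multifunctionality(fn, n_dims = 3)
write.table(data.frame(sample_id = names(mf$average_mf),
                       position = meta$position[match(names(mf$average_mf),
                                                      meta$sample_id)],
                       average_mf = mf$average_mf, mf$dim_scores,
                       check.names = FALSE),
            file.path(out, "multifunctionality.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Principal axes of the 12 ecosystem functions:\n")
cat(sprintf("  dim %d: %.1f%% of variance\n", 1:3,
            100 * mf$explained_variance))
pos <- meta$position[match(names(mf$average_mf), meta$sample_id)]
avg <- tapply(mf$average_mf, factor(pos, c("top", "middle", "bottom")), mean)
cat("Average multifunctionality by position:\n")
print(round(avg, 3))
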