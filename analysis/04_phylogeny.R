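#!/usr/bin/env Rscript
# Allele-sharing distances and midpoint-rooted neighbour-joining tree for
# the simulated cohort from step 01. Outputs go to results/tree/.

suppressMessages(library(rohdiv))
dir.create("results/tree", recursive = TRUE, showWarnings = FALSE)

x <- read_vcf("results/data/cohort.vcf")
imap <- read.delim("results/data/island_map.tsv")

dm <- allele_sharing_distance(x)
write.table(round(dm$dist, 6), "results/tree/distances.tsv", sep = "\t",
            quote = FALSE)
tree <- midpoint_root(neighbor_joining(dm$dist))
ape::write.tree(tree, "results/tree/cohort.nwk")

pan <- imap$sample[imap$island == "panay"]
neg <- imap$sample[imap$island == "negros"]
cat(sprintf("mean within-island distance: panay %.4f, negros %.4f\n",
            mean(dm$dist[pan, pan][upper.tri(dm$dist[pan, pan])]),
            mean(dm$dist[neg, neg][upper.tri(dm$dist[neg, neg])])))
cat(sprintf("mean between-island distance: %.4f\n",
            mean(dm$dist[pan, neg])))
cat(sprintf("panay clade: %s; negros clade: %s\n",
            ape::is.monophyletic(tree, pan),
            ape::is.monophyletic(tree, neg)))
cat("tree:", ape::write.tree(tree), "\n")
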