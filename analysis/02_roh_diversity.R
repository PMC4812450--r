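#!/usr/bin/env Rscript
# ROH detection and nucleotide diversity on the simulated genome from step
# 01, plus cohort summaries recomputed from the published per-individual
# table. Outputs go to results/tables/ and results/roh/.

suppressMessages(library(rohdiv))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/roh", recursive = TRUE, showWarnings = FALSE)

## Simulated genome: filter, bin, scale, call, summarise -------------------
x <- read_vcf("results/data/individual.vcf")
cov <- read.delim("results/data/individual_coverage.tsv")
# the simulation's depth is known to be 10x; the window is 5x-20x
x <- filter_depth(x, means = c(S1 = 10))
track <- bin_genome(x, "S1", c(chr1 = 30e6),
                    coverage = cov[cov$sample == "S1", ])
track <- filter_bins(scale_bins(track))
rohs <- call_rohs(track)
truth <- read.table("results/data/truth_tracts.bed",
                    col.names = c("chrom", "start", "end"))

cat(sprintf("genomic average: %.2f scaled SNPs/bin; cutoff %.2f\n",
            genomic_average(track), 0.33 * genomic_average(track)))
cat(sprintf("called %d ROHs (planted %d); pi outside ROHs = %.2f (lambda = 12)\n",
            nrow(rohs), nrow(truth),
            diversity_outside(track, rohs)))
for (k in seq_len(nrow(truth))) {
  ov <- rohs[rohs$end > truth$start[k] & rohs$start < truth$end[k], ]
  cat(sprintf("  tract %d [%d, %d): recovered %s\n", k, truth$start[k],
              truth$end[k],
              if (nrow(ov) == 1)
                sprintf("[%d, %d), edge error %.1f/%.1f bins",
                        ov$start, ov$end,
                        abs(ov$start - truth$start[k]) / 1e4,
                        abs(ov$end - truth$end[k]) / 1e4)
              else "NO"))
}
write.table(rohs, "results/roh/called_rohs.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(roh_summary(track, rohs), "results/roh/sample_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(classify_lengths(rohs), "results/roh/length_categories.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## Published per-individual table: cohort and island summaries -------------
pub <- sus_roh_summary()
ceb <- pub[pub$species == "Sus cebifrons", ]
other <- pub[pub$group == "other", ]
overall <- summarize_cohort(ceb)
islands <- summarize_cohort(ceb, group = ceb$group)
others <- summarize_cohort(other)
summary_tab <- rbind(cbind(cohort = "S. cebifrons", overall[, -1]),
                     cbind(cohort = paste0("S. cebifrons (", islands$group,
                                           ")"), islands[, -1]),
                     cbind(cohort = "other Sus", others[, -1]))
write.table(summary_tab, "results/tables/cohort_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\ncohort ROH count: %.0f +/- %.0f (Panay %.0f, Negros %.0f)\n",
            round_half_away(overall$mean_n_rohs),
            round_half_away(overall$sd_n_rohs),
            round_half_away(islands$mean_n_rohs[islands$group == "panay"]),
            round_half_away(islands$mean_n_rohs[islands$group == "negros"])))
cat(sprintf("mean ROH length: %.1f Mb; pi: %.0f (S. cebifrons) vs %.0f (other Sus)\n",
            round_half_away(overall$mean_mean_length_kb / 1000, 1),
            round_half_away(overall$mean_pi),
            round_half_away(others$mean_pi)))
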