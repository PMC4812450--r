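#!/usr/bin/env Rscript
# Generate the synthetic study data used by the downstream analysis steps:
# one diploid genome with planted autozygous tracts, a two-island cohort
# with known shared/private variant counts, and textbook pedigrees.
# Outputs go to results/data/ (VCF, coverage TSV, truth BED, studbook CSV).

suppressMessages(library(rohdiv))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## One genome: 30 Mb autosome at the warty-pig diversity level (12 het
## SNPs / 10 kb), three planted tracts spanning the short-to-long ROH range
tracts <- data.frame(chrom = "chr1",
                     start = c(3003000, 11050000, 20007000),
                     end = c(3303000, 11550000, 21007000))
cfg <- sim_config(c(chr1 = 30e6), het_rate_per_bin = 12,
                  tract_residual_factor = 0.02, planted_tracts = tracts,
                  mean_depth = 10)
sim <- simulate_individual(cfg, seed = seed)
write_vcf(sim$variants, "results/data/individual.vcf",
          contig_lengths = c(chr1 = 30e6))
write.table(cbind(sample = "S1", sim$coverage),
            "results/data/individual_coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth[, c("chrom", "start", "end")],
            "results/data/truth_tracts.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
cat(sprintf("individual genome: %d heterozygous sites, %d planted tracts\n",
            n_sites(sim$variants), nrow(tracts)))

## Cohort: 5 Panay + 2 Negros samples, 1000 shared and 115/63 private sites
## (island-specific fraction ~15%, as in the study system)
co <- simulate_cohort(5, 2, 1000, 115, 63, seed = seed + 1L)
write_vcf(co$variants, "results/data/cohort.vcf",
          contig_lengths = c(chr1 = 1e7))
write.table(data.frame(sample = names(co$island_map),
                       island = unname(co$island_map)),
            "results/data/island_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(chrom = co$variants$sites$chrom,
                       pos = co$variants$sites$pos,
                       category = co$truth),
            "results/data/cohort_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("cohort: %d sites (%s)\n", n_sites(co$variants),
            paste(names(table(co$truth)), table(co$truth),
                  sep = "=", collapse = ", ")))

## Pedigrees: the four textbook mating schemes
for (design in c("outbred", "full_sib", "half_sib", "first_cousin")) {
  ped <- simulate_pedigree(design)
  write.csv(as.data.frame(ped)[, c("id", "sire", "dam", "birth_date")],
            sprintf("results/data/pedigree_%s.csv", design),
            row.names = FALSE)
}
cat("pedigrees written for four mating schemes\n")
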