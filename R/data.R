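#' Published per-individual ROH and diversity summaries for Sus genomes
#'
#' The per-individual whole-genome summaries reported for seven captive
#' Visayan warty pigs (Sus cebifrons; five sampled from the Panay-descended
#' breeding programme, two from the Negros-descended one) and ten other Sus
#' genomes analysed with the same criteria: pedigree inbreeding coefficient
#' (where a studbook exists), number of ROHs of more than 20 bins, mean ROH
#' length (kb), and nucleotide diversity outside ROHs (scaled heterozygous
#' SNPs per 10-kb bin). These are the inputs for the cohort-level summaries
#' (\code{\link{summarize_cohort}}); the underlying whole-genome
#' computation requires the original resequencing data.
#'
#' @return data.frame with columns \code{sample}, \code{species},
#'   \code{group} (\code{panay}, \code{negros}, \code{other}), \code{sex},
#'   \code{pedigree_F}, \code{n_rohs}, \code{mean_length_kb}, \code{pi}
#' @export
sus_roh_summary <- function() {
  utils::read.delim(system.file("extdata", "sus_roh_summary.tsv",
                                package = "rohdiv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published shared/island-private variant partition for Sus cebifrons
#'
#' The reported partition of cohort SNPs (fixed differences against the
#' Sus scrofa reference excluded, minor allele count at least 2 of the 14
#' haplotypes) into variants shared between the Panay and Negros samples
#' and variants private to either island, for all SNPs and for the coding
#' consequence classes.
#'
#' @return data.frame with columns \code{class} (\code{all},
#'   \code{synonymous}, \code{nonsyn_tolerated},
#'   \code{nonsyn_not_tolerated}), \code{shared}, \code{panay_private},
#'   \code{negros_private}
#' @export
sus_variant_partition <- function() {
  utils::read.delim(system.file("extdata", "sus_variant_partition.tsv",
                                package = "rohdiv"),
                    stringsAsFactors = FALSE)
}
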