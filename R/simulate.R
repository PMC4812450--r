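#' Configuration for the single-genome simulator
#'
#' Describes a diploid genome whose heterozygous sites arise from a Poisson
#' process: rate \code{het_rate_per_bin} per 10-kb bin outside autozygous
#' tracts and \code{tract_residual_factor} times that rate inside them
#' (autozygous tracts are not perfectly SNP-free in real data: residual
#' heterozygosity comes from genotyping error and recent mutation).
#' Coverage is modelled per site around \code{mean_depth}, with whole bins
#' dropping out at probability \code{dropout_prob}.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param het_rate_per_bin expected heterozygous SNPs per 10-kb bin outside
#'   tracts (lambda; the study system shows ~12)
#' @param tract_residual_factor fraction of lambda remaining inside
#'   tracts (epsilon, in [0, 1))
#' @param planted_tracts data.frame (\code{chrom}, \code{start},
#'   \code{end}; 0-based half-open bp) of autozygous tracts; must lie
#'   within their chromosome and not overlap
#' @param mean_depth expected reads per site
#' @param dropout_prob per-bin probability of total coverage loss
#' @param bin_size bin width (default 10,000 bp)
#' @return a \code{sim_config} list
#' @export
sim_config <- function(chrom_lengths, het_rate_per_bin = 12,
                       tract_residual_factor = 0,
                       planted_tracts = NULL, mean_depth = 10,
                       dropout_prob = 0, bin_size = 10000L) {
  stopifnot(het_rate_per_bin > 0,
            tract_residual_factor >= 0, tract_residual_factor < 1,
            mean_depth > 0, dropout_prob >= 0, dropout_prob <= 1,
            !is.null(names(chrom_lengths)))
  if (is.null(planted_tracts))
    planted_tracts <- data.frame(chrom = character(), start = integer(),
                                 end = integer(), stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(planted_tracts)))
  if (nrow(planted_tracts) > 0) {
    if (!all(planted_tracts$chrom %in% names(chrom_lengths)))
      stop("planted tract on unknown chromosome")
    if (any(planted_tracts$start < 0) ||
        any(planted_tracts$end > chrom_lengths[planted_tracts$chrom]))
      stop("planted tract outside chromosome bounds")
    if (any(planted_tracts$end <= planted_tracts$start))
      stop("planted tract with non-positive length")
    for (ch in unique(planted_tracts$chrom)) {
      tr <- planted_tracts[planted_tracts$chrom == ch, , drop = FALSE]
      tr <- tr[order(tr$start), , drop = FALSE]
      if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
        stop("overlapping planted tracts on ", ch)
    }
  }
  structure(list(chrom_lengths = chrom_lengths,
                 het_rate_per_bin = het_rate_per_bin,
                 tract_residual_factor = tract_residual_factor,
                 planted_tracts = planted_tracts,
                 mean_depth = mean_depth,
                 dropout_prob = dropout_prob,
                 bin_size = as.integer(bin_size)),
            class = "sim_config")
}

# probability that a Poisson(mu) depth lands inside the depth window
# [lower*mu, upper*mu] (bounds inclusive)
depth_window_prob <- function(mu, lower = 0.5, upper = 2.0) {
  lo <- ceiling(lower * mu)
  hi <- floor(upper * mu)
  stats::ppois(hi, mu) - stats::ppois(lo - 1, mu)
}

#' Simulate one diploid genome with planted autozygous tracts
#'
#' Places heterozygous sites by a Poisson process (rate lambda per bin
#' outside tracts, epsilon * lambda inside), assigns each variant a read
#' depth drawn from Poisson(\code{mean_depth}), and emits a per-bin
#' coverage track giving the number of positions whose depth falls inside
#' the 0.5--2.0x depth window — drawn as Binomial(bin_size, p) with p the
#' same window probability that applies to the variants, so that the
#' depth filter and the bin-scaling correction see a mutually consistent
#' genome. Dropout bins get zero coverage and zero-depth variants.
#'
#' @param config a \code{\link{sim_config}}
#' @param seed integer seed; identical (config, seed) gives identical
#'   output
#' @param sample_name sample label in the variant table
#' @return list with \code{variants}: a single-sample
#'   \code{\link{variant_table}} of heterozygous sites; \code{coverage}:
#'   per-bin data.frame (\code{chrom}, \code{start}, \code{covered});
#'   \code{truth}: the planted tracts
#' @export
simulate_individual <- function(config, seed = 1L, sample_name = "S1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  bin <- config$bin_size
  lambda <- config$het_rate_per_bin
  eps <- config$tract_residual_factor
  site_rows <- list()
  cov_rows <- list()
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    n_bins <- as.integer(ceiling(len / bin))
    tr <- config$planted_tracts[config$planted_tracts$chrom == ch, ,
                                drop = FALSE]
    in_tract <- function(pos) {
      if (nrow(tr) == 0) return(rep(FALSE, length(pos)))
      hit <- rep(FALSE, length(pos))
      for (k in seq_len(nrow(tr)))
        hit <- hit | (pos > tr$start[k] & pos <= tr$end[k])
      hit
    }
    # thinning: draw at the outside rate genome-wide, keep inside-tract
    # sites with probability eps
    n_exp <- stats::rpois(1, lambda * len / bin)
    pos <- sort(sample.int(len, min(n_exp, len)))
    inside <- in_tract(pos)
    keep <- !inside | stats::runif(length(pos)) < eps
    pos <- pos[keep]
    dropout <- stats::runif(n_bins) < config$dropout_prob
    p_win <- depth_window_prob(config$mean_depth)
    covered <- stats::rbinom(n_bins, bin, p_win)
    # last bin may be shorter than bin_size
    last_len <- len - (n_bins - 1L) * bin
    if (last_len < bin)
      covered[n_bins] <- stats::rbinom(1, last_len, p_win)
    covered[dropout] <- 0L
    if (length(pos) > 0) {
      dp <- stats::rpois(length(pos), config$mean_depth)
      bin_idx <- floor((pos - 1) / bin) + 1L
      dp[dropout[bin_idx]] <- 0L
      site_rows[[ch]] <- data.frame(chrom = ch, pos = pos, dp = dp,
                                    stringsAsFactors = FALSE)
    }
    cov_rows[[ch]] <- data.frame(chrom = ch,
                                 start = (seq_len(n_bins) - 1L) * bin,
                                 covered = covered,
                                 stringsAsFactors = FALSE)
  }
  sites <- if (length(site_rows) > 0) do.call(rbind, site_rows)
           else data.frame(chrom = character(), pos = integer(),
                           dp = integer(), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  gt <- matrix(rep(1L, nrow(sites)), ncol = 1,
               dimnames = list(NULL, sample_name))
  dp <- matrix(sites$dp, ncol = 1, dimnames = list(NULL, sample_name))
  vt <- variant_table(
    data.frame(chrom = sites$chrom, pos = sites$pos,
               ref = rep("A", nrow(sites)), alt = rep("C", nrow(sites)),
               stringsAsFactors = FALSE),
    gt, dp)
  list(variants = vt,
       coverage = do.call(rbind, cov_rows),
       truth = config$planted_tracts)
}

#' Simulate a two-island cohort with known shared and private variants
#'
#' Builds a multi-sample variant table in which exactly \code{n_shared}
#' sites carry the minor allele on both islands and exactly
#' \code{n_panay_private} / \code{n_negros_private} sites carry it only on
#' the respective island. Shared variants are given island-specific
#' intermediate frequencies (each island's carrier probability drawn
#' uniformly from \code{carrier_prob_range} per site, emulating drift since
#' the split); every sample is a heterozygous carrier with its island's
#' probability, redrawn until each island has at least one carrier (so the
#' site is shared, and the minor allele count is at least 2).
#' Private variants are island-diagnostic: every sample of the island is
#' heterozygous (or homozygous-alternate when the island has a single
#' sample), so they differentiate the islands and the minor allele count
#' is at least 2. The partition is therefore recoverable exactly, and an
#' island's samples resemble each other more than they resemble the other
#' island's.
#'
#' @param n_panay,n_negros samples per island (>= 1)
#' @param n_shared,n_panay_private,n_negros_private site counts (>= 0)
#' @param seed integer seed
#' @param chrom_length chromosome length the sites are scattered over
#' @param mean_depth Poisson mean for the emitted DP values
#' @param carrier_prob_range range the per-island carrier probability at
#'   shared sites is drawn from
#' @return list with \code{variants}: the cohort
#'   \code{\link{variant_table}}; \code{truth}: per-site category
#'   (\code{shared}, \code{panay_private}, \code{negros_private});
#'   \code{island_map}: named sample-to-island vector
#' @export
simulate_cohort <- function(n_panay, n_negros, n_shared, n_panay_private,
                            n_negros_private, seed = 1L,
                            chrom_length = 1e7, mean_depth = 10,
                            carrier_prob_range = c(0.2, 0.8)) {
  stopifnot(n_panay >= 1, n_negros >= 1, n_shared >= 0,
            n_panay_private >= 0, n_negros_private >= 0)
  set.seed(seed)
  panay <- paste0("P", seq_len(n_panay))
  negros <- paste0("N", seq_len(n_negros))
  samp <- c(panay, negros)
  island_map <- stats::setNames(rep(c("panay", "negros"),
                                    c(n_panay, n_negros)), samp)
  n_tot <- n_shared + n_panay_private + n_negros_private
  pos <- sort(sample.int(chrom_length, n_tot))
  category <- sample(rep(c("shared", "panay_private", "negros_private"),
                         c(n_shared, n_panay_private, n_negros_private)))
  gt <- matrix(0L, n_tot, length(samp), dimnames = list(NULL, samp))
  draw_shared <- function() {
    q <- stats::runif(2, carrier_prob_range[1], carrier_prob_range[2])
    p_site <- rep(q, c(n_panay, n_negros))
    repeat {
      carrier <- stats::runif(length(samp)) < p_site
      if (any(carrier[seq_len(n_panay)]) &&
          any(carrier[n_panay + seq_len(n_negros)]))
        return(as.integer(carrier))
    }
  }
  private_row <- function(members) {
    row <- rep(0L, length(samp))
    # island-diagnostic: every member carries; a lone sample is made
    # homozygous so the minor allele count still reaches 2
    row[match(members, samp)] <- if (length(members) >= 2) 1L else 2L
    row
  }
  for (k in seq_len(n_tot)) {
    gt[k, ] <- switch(category[k],
                      shared = draw_shared(),
                      panay_private = private_row(panay),
                      negros_private = private_row(negros))
  }
  dp <- matrix(stats::rpois(n_tot * length(samp), mean_depth),
               n_tot, length(samp), dimnames = list(NULL, samp))
  vt <- variant_table(
    data.frame(chrom = rep("chr1", n_tot), pos = pos,
               ref = rep("A", n_tot), alt = rep("C", n_tot),
               stringsAsFactors = FALSE),
    gt, dp)
  list(variants = vt, truth = category, island_map = island_map)
}

#' Simulate a textbook pedigree with known inbreeding coefficient
#'
#' Returns a studbook-format pedigree whose focal (last) individual has the
#' textbook inbreeding coefficient of the named mating scheme:
#' \code{full_sib} F = 1/4, \code{half_sib} F = 1/8, \code{first_cousin}
#' F = 1/16, \code{outbred} F = 0. Birth dates step by 5 years per
#' generation.
#'
#' @param design one of \code{"full_sib"}, \code{"half_sib"},
#'   \code{"first_cousin"}, \code{"outbred"}
#' @param seed accepted for interface symmetry; the pedigrees are fixed
#' @return a \code{pedigree} data.frame (see \code{\link{read_studbook}})
#'   with attribute \code{"focal"} naming the focal individual
#' @export
simulate_pedigree <- function(design = c("full_sib", "half_sib",
                                         "first_cousin", "outbred"),
                              seed = 1L) {
  design <- match.arg(design)
  y <- function(g) sprintf("%d-01-01", 2000 + 5 * g)
  rows <- switch(design,
    outbred = data.frame(
      id = c("A", "B", "X"),
      sire = c("WILD", "WILD", "A"),
      dam = c("WILD", "WILD", "B"),
      birth_date = c(y(0), y(0), y(1))),
    full_sib = data.frame(
      id = c("A", "B", "C", "D", "X"),
      sire = c("WILD", "WILD", "A", "A", "C"),
      dam = c("WILD", "WILD", "B", "B", "D"),
      birth_date = c(y(0), y(0), y(1), y(1), y(2))),
    half_sib = data.frame(
      id = c("A", "B", "C", "P", "Q", "X"),
      sire = c("WILD", "WILD", "WILD", "A", "A", "P"),
      dam = c("WILD", "WILD", "WILD", "B", "C", "Q"),
      birth_date = c(y(0), y(0), y(0), y(1), y(1), y(2))),
    first_cousin = data.frame(
      id = c("A", "B", "C", "D", "E", "F", "P", "Q", "X"),
      sire = c("WILD", "WILD", "WILD", "WILD", "A", "A", "E", "F", "P"),
      dam = c("WILD", "WILD", "WILD", "WILD", "B", "B", "C", "D", "Q"),
      birth_date = c(y(0), y(0), y(0), y(0), y(1), y(1), y(2), y(2), y(3))))
  ped <- read_studbook(rows)
  attr(ped, "focal") <- "X"
  ped
}
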