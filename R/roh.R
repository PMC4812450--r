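#' Tile a genome into fixed bins and count heterozygous SNPs per bin
#'
#' Bins each chromosome into adjacent, non-overlapping windows of
#' \code{bin_size} bp (default 10 kb) and counts, for one sample, the
#' heterozygous sites falling in each bin. Heterozygosity per bin is the
#' raw signal the ROH caller thresholds: autozygous tracts show up as runs
#' of bins with (near-)zero heterozygous SNPs.
#'
#' Bin boundaries are 0-based half-open; a 1-based site at position p lands
#' in bin \code{floor((p - 1) / bin_size)}, so position 10,000 belongs to
#' the first bin \code{[0, 10000)}.
#'
#' @param x a depth-filtered \code{\link{variant_table}}
#' @param sample sample whose heterozygous sites are counted
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param coverage per-bin callability: data.frame with columns
#'   \code{chrom}, \code{start}, \code{covered} giving the number of
#'   positions per bin whose depth lies inside the sample's depth window
#'   (e.g. the simulator's depth track, or a per-bin reduction of a
#'   BED-graph). \code{NULL} treats every bin as fully covered.
#' @param bin_size bin width in bp (default 10,000)
#' @return a bin track data.frame: \code{chrom}, \code{start}, \code{end},
#'   \code{covered_sites}, \code{raw_snp_count}, \code{scaled_snp_count}
#'   (NA until \code{\link{scale_bins}}), \code{retained} (NA until
#'   \code{\link{filter_bins}})
#' @export
bin_genome <- function(x, sample, chrom_lengths, coverage = NULL,
                       bin_size = 10000L) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  tracks <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_bins <- as.integer(ceiling(len / bin_size))
    start <- (seq_len(n_bins) - 1L) * as.integer(bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + as.integer(bin_size), as.integer(len)),
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, tracks)
  key <- function(chrom, bin_start) paste(chrom, bin_start, sep = ":")
  track$covered_sites <- as.integer(pmin(track$end - track$start, bin_size))
  if (!is.null(coverage)) {
    stopifnot(all(c("chrom", "start", "covered") %in% names(coverage)))
    idx <- match(key(track$chrom, track$start),
                 key(coverage$chrom, coverage$start))
    track$covered_sites <- ifelse(is.na(idx), 0L,
                                  as.integer(coverage$covered[idx]))
  }
  het <- x$gt[, sample] == 1L & !is.na(x$gt[, sample])
  hs <- x$sites[het, , drop = FALSE]
  keep <- hs$chrom %in% names(chrom_lengths)
  hs <- hs[keep, , drop = FALSE]
  if (nrow(hs) > 0 &&
      any(hs$pos > chrom_lengths[hs$chrom]))
    stop("heterozygous site beyond chromosome length")
  bin_start <- as.integer(floor((hs$pos - 1) / bin_size) * bin_size)
  counts <- table(key(hs$chrom, bin_start))
  track$raw_snp_count <- 0L
  m <- match(key(track$chrom, track$start), names(counts))
  track$raw_snp_count[!is.na(m)] <- as.integer(counts[m[!is.na(m)]])
  track$scaled_snp_count <- NA_real_
  track$retained <- NA
  attr(track, "bin_size") <- as.integer(bin_size)
  track
}

#' Scale per-bin SNP counts up from covered sites to the full bin
#'
#' Corrects for missing (uncallable) positions by extrapolating the observed
#' SNP count from the covered fraction of a bin to its full length:
#' \code{scaled = raw * bin_size / covered_sites}. Without this correction,
#' poorly covered bins would mimic low heterozygosity and inflate ROH calls.
#' Bins with zero covered sites carry no information and are marked not
#' retained.
#'
#' @param track a bin track from \code{\link{bin_genome}}
#' @return the track with \code{scaled_snp_count} filled in
#' @export
scale_bins <- function(track) {
  bin_size <- attr(track, "bin_size")
  if (is.null(bin_size)) bin_size <- 10000L
  ok <- track$covered_sites > 0L
  track$scaled_snp_count <- ifelse(
    ok, track$raw_snp_count * bin_size / track$covered_sites, NA_real_)
  track$retained <- ok
  track
}

#' Exclude unreliable bins: low coverage and sex chromosomes
#'
#' A bin is retained iff at least \code{min_covered} of its positions are
#' callable (default 1,000, i.e. 10\% of a 10-kb bin; a bin with 999 covered
#' sites is excluded, one with exactly 1,000 passes) and its chromosome is
#' autosomal. Sex chromosomes are excluded because their recombination
#' landscape differs from the autosomes.
#'
#' @param track a scaled bin track
#' @param sex_chroms chromosomes to exclude (default \code{c("X","Y")})
#' @param min_covered minimum callable positions per bin
#' @return the track with \code{retained} finalised
#' @export
filter_bins <- function(track, sex_chroms = c("X", "Y"),
                        min_covered = 1000L) {
  track$retained <- track$covered_sites >= min_covered &
    !(track$chrom %in% sex_chroms)
  track
}

#' Genome-wide average scaled SNP count per bin
#'
#' Arithmetic mean of \code{scaled_snp_count} over all retained bins,
#' including bins that will later fall inside ROHs: the average is defined
#' before any ROH exists, so excluding them would be circular.
#'
#' @param track a filtered, scaled bin track
#' @return mean scaled SNPs per bin (double)
#' @export
genomic_average <- function(track) {
  s <- track$scaled_snp_count[track$retained %in% TRUE]
  if (length(s) == 0L) stop("no retained bins")
  mean(s)
}

#' Call runs of homozygosity from a bin track
#'
#' A ROH is a maximal run of at least \code{min_bins} consecutive retained
#' bins whose scaled SNP count is strictly below \code{frac} times the
#' genomic average (with an average of 12, the cutoff is 3.96: a bin at
#' 3.96 does not qualify, one at 3.95 does). A non-retained bin (low
#' coverage or sex chromosome) terminates a run; \code{max_gap_bins}
#' retained non-qualifying bins may optionally be bridged (default 0,
#' i.e. strictly consecutive).
#'
#' @param track a filtered, scaled bin track
#' @param genomic_avg the genome-wide average scaled SNP count; computed
#'   from \code{track} when \code{NULL}
#' @param min_bins minimum run length in bins (default 20)
#' @param frac fraction of the genomic average defining the cutoff
#'   (default 0.33)
#' @param max_gap_bins retained non-qualifying bins tolerated inside a run
#' @return data.frame of ROH segments: \code{chrom}, \code{start},
#'   \code{end} (bp, 0-based half-open), \code{n_bins}, \code{length}
#' @export
call_rohs <- function(track, genomic_avg = NULL, min_bins = 20L,
                      frac = 0.33, max_gap_bins = 0L) {
  if (is.null(genomic_avg)) genomic_avg <- genomic_average(track)
  stopifnot(genomic_avg > 0)
  cutoff <- frac * genomic_avg
  bin_size <- attr(track, "bin_size")
  if (is.null(bin_size)) bin_size <- 10000L
  qual <- track$retained %in% TRUE &
    !is.na(track$scaled_snp_count) & track$scaled_snp_count < cutoff
  out <- list()
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch)
    sel <- sel[order(track$start[sel])]
    q <- qual[sel]
    ret <- track$retained[sel] %in% TRUE
    runs <- roh_runs(q, ret, min_bins, max_gap_bins)
    if (nrow(runs) > 0) {
      out[[ch]] <- data.frame(
        chrom = ch,
        start = track$start[sel[runs$first]],
        end = track$end[sel[runs$last]],
        n_bins = runs$last - runs$first + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_bins = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$length <- res$end - res$start
  res
}

# run finder on a single chromosome's qualifying/retained flags;
# returns first/last bin indices of each accepted run
roh_runs <- function(qual, retained, min_bins, max_gap_bins) {
  n <- length(qual)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!qual[i]) { i <- i + 1L; next }
    j <- i
    end_run <- i
    gap <- 0L
    while (j < n) {
      nxt <- j + 1L
      if (qual[nxt]) {
        j <- nxt; end_run <- nxt; gap <- 0L
      } else if (retained[nxt] && gap < max_gap_bins) {
        j <- nxt; gap <- gap + 1L
      } else break
    }
    if (end_run - i + 1L >= min_bins) {
      first <- c(first, i); last <- c(last, end_run)
    }
    i <- j + 1L
  }
  data.frame(first = first, last = last)
}

#' Bin a set of ROHs into length categories
#'
#' Assigns each ROH to one length category under a half-open
#' \code{[lo, hi)} convention (a ROH of exactly 0.5 Mb falls in the
#' 0.5--1 Mb class); the top category is unbounded. Short ROHs reflect older
#' inbreeding, long ROHs recent consanguineous matings, so the length
#' spectrum summarises when autozygosity arose.
#'
#' @param rohs ROH segments from \code{\link{call_rohs}}
#' @param edges ascending category edges in bp
#'   (default 0.2, 0.5, 1, 2, 5 Mb)
#' @return data.frame per category: \code{category}, \code{n_rohs},
#'   \code{total_bp}
#' @export
classify_lengths <- function(rohs, edges = c(0.2, 0.5, 1, 2, 5) * 1e6) {
  stopifnot(length(edges) >= 1, !is.unsorted(edges, strictly = TRUE))
  if (nrow(rohs) > 0 && any(rohs$length < edges[1]))
    stop("ROH shorter than the smallest category edge")
  mb <- function(e) {
    x <- e / 1e6
    ifelse(x == round(x), sprintf("%d", as.integer(round(x))),
           sub("0+$", "", sprintf("%.2f", x)))
  }
  labels <- c(paste0(mb(edges[-length(edges)]), "-", mb(edges[-1]), " Mb"),
              paste0(">=", mb(edges[length(edges)]), " Mb"))
  idx <- findInterval(rohs$length, edges)  # [lo, hi) by default
  data.frame(
    category = labels,
    n_rohs = vapply(seq_along(labels),
                    function(k) sum(idx == k), integer(1)),
    total_bp = vapply(seq_along(labels),
                      function(k) sum(as.numeric(rohs$length[idx == k])),
                      numeric(1)),
    stringsAsFactors = FALSE)
}

#' Nucleotide diversity outside ROHs
#'
#' The mean scaled SNP count per retained bin lying outside every called
#' ROH: the study's per-individual diversity measure (pi), in units of
#' heterozygous SNPs per 10-kb bin. With no ROHs it equals the genomic
#' average.
#'
#' @param track a filtered, scaled bin track
#' @param rohs ROH segments from \code{\link{call_rohs}}
#' @return pi, scaled SNPs per bin (double)
#' @export
diversity_outside <- function(track, rohs) {
  inside <- rep(FALSE, nrow(track))
  for (k in seq_len(nrow(rohs))) {
    inside <- inside | (track$chrom == rohs$chrom[k] &
                        track$start >= rohs$start[k] &
                        track$start < rohs$end[k])
  }
  s <- track$scaled_snp_count[track$retained %in% TRUE & !inside]
  if (length(s) == 0L) stop("every retained bin lies inside a ROH")
  mean(s)
}

#' Per-sample ROH and diversity summary
#'
#' @param track a filtered, scaled bin track for one sample
#' @param rohs that sample's called ROHs
#' @param edges length-category edges passed to
#'   \code{\link{classify_lengths}}
#' @return a one-row data.frame: \code{n_rohs}, \code{mean_length_kb},
#'   \code{pi}, plus one genome-fraction column per length category
#'   (denominator: total bp tiled by the track)
#' @export
roh_summary <- function(track, rohs, edges = c(0.2, 0.5, 1, 2, 5) * 1e6) {
  genome_bp <- sum(as.numeric(track$end - track$start))
  cls <- classify_lengths(rohs, edges)
  frac <- cls$total_bp / genome_bp
  names(frac) <- paste0("frac_", gsub("[^0-9A-Za-z.>=]+", "_", cls$category))
  out <- data.frame(
    n_rohs = nrow(rohs),
    mean_length_kb = if (nrow(rohs) > 0) mean(rohs$length) / 1000 else NA_real_,
    pi = diversity_outside(track, rohs))
  cbind(out, as.data.frame(as.list(frac)))
}

#' Cohort summary: group means and standard deviations
#'
#' Summarises per-sample statistics (ROH count, mean ROH length, diversity
#' outside ROHs) per group and over all samples, as arithmetic mean and
#' sample standard deviation. A single-sample group has no defined SD and
#' reports \code{NA}.
#'
#' @param stats data.frame with one row per sample and columns
#'   \code{n_rohs}, \code{mean_length_kb}, \code{pi}
#' @param group vector assigning each row to a group; \code{NULL} summarises
#'   the whole cohort as one group \code{"all"}
#' @return data.frame per group: \code{group}, \code{n}, then
#'   \code{mean_}/\code{sd_} columns for each statistic
#' @export
summarize_cohort <- function(stats, group = NULL) {
  vars <- c("n_rohs", "mean_length_kb", "pi")
  vars <- vars[vars %in% names(stats)]
  if (length(vars) == 0L) stop("no summary columns found")
  if (is.null(group)) group <- rep("all", nrow(stats))
  if (length(group) != nrow(stats))
    stop("group must have one entry per sample")
  if (nrow(stats) == 0L) stop("empty cohort")
  res <- lapply(unique(group), function(g) {
    sub <- stats[group == g, , drop = FALSE]
    row <- data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE)
    for (v in vars) {
      row[[paste0("mean_", v)]] <- mean(sub[[v]])
      row[[paste0("sd_", v)]] <- if (nrow(sub) > 1) stats::sd(sub[[v]])
                                 else NA_real_
    }
    row
  })
  do.call(rbind, res)
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 rounds up in magnitude), matching how the
#' cohort summaries are reported as integers; base \code{round} rounds half
#' to even.
#'
#' @param x numeric
#' @param digits decimal places (default 0)
#' @return rounded numeric
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
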