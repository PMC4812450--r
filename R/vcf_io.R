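#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF (v4.x, plain or bgzipped) with per-sample GT, and DP where
#' present, into the package's \code{\link{variant_table}} container. Record
#' order is preserved. Multi-allelic records are passed through and flagged
#' so that \code{\link{select_biallelic}} can drop them later; they are never
#' silently removed here.
#'
#' @param path path to a VCF file.
#' @return a \code{\link{variant_table}}.
#' @details Every record must carry GT in its FORMAT; a record without GT is
#'   an error reporting the record number. Absent DP yields \code{NA} depth.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    samp <- setdiff(colnames(v@gt), "FORMAT")
    if (length(samp) == 0L) samp <- "S1"
    empty <- matrix(NA_integer_, 0L, length(samp),
                    dimnames = list(NULL, samp))
    return(variant_table(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    stringsAsFactors = FALSE),
                         empty, empty))
  }
  fmt <- v@gt[, "FORMAT"]
  no_gt <- !vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (any(no_gt))
    stop("record ", which(no_gt)[1], ": FORMAT has no GT field")
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos))
    stop("record ", which(is.na(pos))[1], ": malformed POS")
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
               dimnames = dimnames(gt_chr))
  alleles <- gsub("\\|", "/", gt_chr)
  gt[alleles %in% c("0/0")] <- 0L
  gt[alleles %in% c("0/1", "1/0")] <- 1L
  gt[alleles %in% c("1/1")] <- 2L
  # multi-allelic genotype calls (e.g. 1/2) stay NA-coded until the record
  # is removed by select_biallelic
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dp)) {
    dp <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = pos,
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, dp)
}

#' Write a variant table as a plain-text VCF v4.2
#'
#' Emits GT and DP FORMAT fields. Intended for interchange with external
#' tools and for fixtures; the writer is deliberately minimal (no INFO).
#'
#' @param x a \code{\link{variant_table}}
#' @param path output path
#' @param contig_lengths optional named vector of chromosome lengths for
#'   \code{##contig} header lines
#' @return \code{path}, invisibly
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
             con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(contig_lengths), as.integer(contig_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples(x)), collapse = "\t"), con)
  if (n_sites(x) == 0L) return(invisible(path))
  gt_str <- matrix("./.", n_sites(x), length(samples(x)))
  gt_str[x$gt == 0L & !is.na(x$gt)] <- "0/0"
  gt_str[x$gt == 1L & !is.na(x$gt)] <- "0/1"
  gt_str[x$gt == 2L & !is.na(x$gt)] <- "1/1"
  dp_str <- ifelse(is.na(x$dp), ".", as.character(x$dp))
  cell <- matrix(paste(gt_str, dp_str, sep = ":"),
                 n_sites(x), length(samples(x)))
  lines <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                 ".", "PASS", ".", "GT:DP",
                 apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Mean read depth of one sample
#'
#' Arithmetic mean of the per-site depths with non-missing DP; the reference
#' point for the depth-window filter.
#'
#' @param x a \code{\link{variant_table}}
#' @param sample sample name
#' @return mean depth (double)
#' @export
mean_depth <- function(x, sample) {
  d <- x$dp[, sample]
  d <- d[!is.na(d)]
  if (length(d) == 0L)
    stop("no depth data for sample ", sample)
  mean(d)
}

#' Depth-window filter: mask genotypes with unreliable read depth
#'
#' A site is retained for a sample iff its depth lies between
#' \code{lower * mean} and \code{upper * mean} of that sample's own mean
#' depth, bounds inclusive (with a 10x mean, depths 5 and 20 both pass).
#' Sites below the window are low-reliability calls, sites above it likely
#' sequencing artefacts or copy-number variants. Filtering is per-sample
#' masking (genotype and depth set to missing), not whole-record dropping:
#' each genome is filtered against its own average. Missing depth is treated
#' as outside the window.
#'
#' @param x a \code{\link{variant_table}}
#' @param lower,upper window bounds as multiples of the sample mean
#'   (defaults 0.5 and 2.0)
#' @param sample samples to filter; default all
#' @param means optional named vector of per-sample mean depths to use as the
#'   window reference instead of recomputing from \code{x}
#' @return the filtered \code{variant_table}, carrying the window reference
#'   means in its \code{"depth_means"} attribute. A table that already
#'   carries that attribute is re-filtered against the same reference, so
#'   the filter is idempotent.
#' @export
filter_depth <- function(x, lower = 0.5, upper = 2.0, sample = samples(x),
                         means = NULL) {
  stopifnot(0 < lower, lower < upper)
  if (is.null(means)) means <- attr(x, "depth_means")
  used <- numeric(0)
  for (s in sample) {
    m <- if (!is.null(means) && s %in% names(means)) means[[s]]
         else mean_depth(x, s)
    d <- x$dp[, s]
    drop <- is.na(d) | d < lower * m | d > upper * m
    x$gt[drop, s] <- NA_integer_
    x$dp[drop, s] <- NA_integer_
    used[s] <- m
  }
  attr(x, "depth_means") <- used
  x
}

#' Keep biallelic, cohort-variant sites
#'
#' Retains only sites with exactly one alternate allele and at least one
#' non-reference genotype in the cohort; multi-allelic records and sites
#' where every called genotype is homozygous reference are removed.
#'
#' @param x a \code{\link{variant_table}}
#' @return the filtered \code{variant_table}
#' @export
select_biallelic <- function(x) {
  one_alt <- !x$sites$multiallelic & !is.na(x$sites$alt) & x$sites$alt != "."
  has_var <- rowSums(x$gt > 0L, na.rm = TRUE) > 0L
  x[one_alt & has_var, ]
}
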