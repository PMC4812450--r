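#' Variant table: genotypes and depths for a set of biallelic sites
#'
#' The canonical in-memory representation used by every stage of the
#' workflow: a site table plus two site-by-sample matrices, one of genotype
#' codes and one of per-sample read depths.
#'
#' Genotypes are coded as integers: \code{0} = homozygous reference,
#' \code{1} = heterozygous, \code{2} = homozygous alternate, \code{NA} =
#' missing (uncalled, or masked by the depth filter).
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}. Multi-allelic records carry a comma-separated
#'   \code{alt} and are flagged in the \code{multiallelic} column.
#' @param gt integer matrix, one row per site, one named column per sample.
#' @param dp integer matrix of per-sample read depths, same shape as
#'   \code{gt}; \code{NA} where depth was not reported.
#'
#' @return An object of class \code{variant_table}.
#' @export
variant_table <- function(sites, gt, dp = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites))
    stop("gt must have one row per site")
  if (is.null(colnames(gt)))
    stop("gt columns must be named by sample")
  if (is.null(dp)) {
    dp <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  dp <- as.matrix(dp)
  if (!identical(dim(dp), dim(gt)))
    stop("dp must have the same shape as gt")
  if (any(sites$pos < 1, na.rm = TRUE))
    stop("positions must be >= 1")
  bad <- !(gt %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!"multiallelic" %in% names(sites))
    sites$multiallelic <- grepl(",", sites$alt, fixed = TRUE)
  storage.mode(gt) <- "integer"
  storage.mode(dp) <- "integer"
  rownames(gt) <- rownames(dp) <- NULL
  colnames(dp) <- colnames(gt)
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              n_sites(x), length(samples(x)),
              paste(utils::head(samples(x), 8), collapse = ", ")))
  invisible(x)
}

#' Number of sites in a variant table
#' @param x a \code{variant_table}
#' @return integer count of sites
#' @export
n_sites <- function(x) nrow(x$sites)

#' Sample names of a variant table
#' @param x a \code{variant_table}
#' @return character vector of sample names
#' @export
samples <- function(x) colnames(x$gt)

#' Subset a variant table by site and/or sample
#'
#' @param x a \code{variant_table}
#' @param i site index (logical or integer)
#' @param j sample index or names
#' @param ... unused
#' @return a \code{variant_table}
#' @export
`[.variant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_sites(x))
  if (missing(j)) j <- seq_along(samples(x))
  variant_table(x$sites[i, , drop = FALSE],
                x$gt[i, j, drop = FALSE],
                x$dp[i, j, drop = FALSE])
}
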