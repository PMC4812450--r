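#' Remove fixed differences against the reference species
#'
#' A site where every called genotype in the cohort is homozygous for the
#' alternate allele is invariant within the study species and reflects only
#' divergence from the reference assembly; such sites are removed (as are
#' sites where every called genotype is homozygous reference, which are not
#' variants at all). The reference-assembly allele stands proxy for the
#' reference species.
#'
#' @param x a \code{\link{variant_table}}
#' @return the filtered \code{variant_table}
#' @export
remove_fixed_differences <- function(x) {
  n_called <- rowSums(!is.na(x$gt))
  all_hom_alt <- n_called > 0L & rowSums(x$gt == 2L, na.rm = TRUE) == n_called
  all_hom_ref <- rowSums(x$gt == 0L, na.rm = TRUE) == n_called
  x[!(all_hom_alt | all_hom_ref), ]
}

# per-site haplotype counts of the alternate allele and of called haplotypes
alt_hap_counts <- function(x) {
  alt <- rowSums(x$gt, na.rm = TRUE)              # het = 1, hom_alt = 2
  total <- 2L * rowSums(!is.na(x$gt))
  list(alt = alt, total = total)
}

# TRUE where the alternate allele is the minor allele; ties go to alt
alt_is_minor <- function(x) {
  h <- alt_hap_counts(x)
  h$alt <= h$total - h$alt
}

#' Minor-allele-count filter
#'
#' Counts the minor allele over all called haplotypes (a heterozygote
#' contributes 1 copy, a homozygote 2) and removes sites where that count
#' falls below \code{min_count}. Singleton alleles (count 1) are likely
#' spurious calls; the default threshold of 2 removes them. When the two
#' alleles tie, the alternate allele is treated as minor.
#'
#' @param x a \code{\link{variant_table}}
#' @param min_count minimum minor allele count (default 2)
#' @return the filtered \code{variant_table}
#' @export
mac_filter <- function(x, min_count = 2L) {
  h <- alt_hap_counts(x)
  mac <- pmin(h$alt, h$total - h$alt)
  x[mac >= min_count, ]
}

#' Classify each site as shared or island-private
#'
#' A site is private to an island iff its minor allele is carried only by
#' samples from that island; a minor allele seen on both islands makes the
#' site shared. Carriers are samples with at least one copy of the minor
#' allele; missing genotypes contribute nothing and can never make a site
#' private on their own.
#'
#' @param x a \code{\link{variant_table}}, already passed through
#'   \code{\link{remove_fixed_differences}} and \code{\link{mac_filter}}
#' @param island_map named character vector mapping every sample to its
#'   island (e.g. \code{c(S1 = "panay", S2 = "negros")}); exactly two
#'   distinct islands are expected
#' @return list with \code{category}: per-site factor in
#'   \code{shared}, \code{<island1>_private}, \code{<island2>_private}; and
#'   \code{counts}: named integer vector of category totals
#' @export
partition_by_island <- function(x, island_map) {
  miss <- setdiff(samples(x), names(island_map))
  if (length(miss) > 0)
    stop("samples not in island map: ", paste(miss, collapse = ", "))
  islands <- sort(unique(unname(island_map[samples(x)])))
  if (length(islands) != 2L)
    stop("expected exactly two islands, got ", length(islands))
  minor_is_alt <- alt_is_minor(x)
  # carrier of the minor allele: >=1 copy of alt when alt is minor,
  # >=1 copy of ref (genotype 0 or 1) when ref is minor
  carrier <- matrix(FALSE, n_sites(x), length(samples(x)))
  carrier[minor_is_alt, ] <- x$gt[minor_is_alt, , drop = FALSE] >= 1L
  carrier[!minor_is_alt, ] <- x$gt[!minor_is_alt, , drop = FALSE] <= 1L
  carrier[is.na(carrier)] <- FALSE
  on_island <- function(isl) {
    cols <- which(island_map[samples(x)] == isl)
    rowSums(carrier[, cols, drop = FALSE]) > 0L
  }
  in1 <- on_island(islands[1])
  in2 <- on_island(islands[2])
  levs <- c("shared", paste0(islands, "_private"))
  category <- factor(ifelse(in1 & in2, levs[1],
                     ifelse(in1, levs[2],
                     ifelse(in2, levs[3], NA))), levels = levs)
  counts <- table(category)
  list(category = category,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Classify sites by consequence and SIFT score
#'
#' Splits annotated sites into synonymous, nonsynonymous-tolerated and
#' nonsynonymous-not-tolerated classes. SIFT scores run from 1 (tolerated)
#' to 0 (deleterious); a nonsynonymous variant with a score strictly below
#' \code{threshold} is called not tolerated (a score of exactly 0.05 is
#' tolerated under the default).
#'
#' @param annot data.frame with columns \code{chrom}, \code{pos},
#'   \code{consequence} (\code{synonymous}, \code{nonsynonymous} or
#'   \code{other}) and \code{sift_score} (nonsynonymous sites only)
#' @param threshold SIFT cutoff (default 0.05)
#' @return the annotation with a \code{class} column added:
#'   \code{synonymous}, \code{nonsyn_tolerated}, \code{nonsyn_not_tolerated}
#'   or \code{other}
#' @export
classify_sift <- function(annot, threshold = 0.05) {
  stopifnot(all(c("chrom", "pos", "consequence") %in% names(annot)))
  ns <- annot$consequence == "nonsynonymous"
  if (any(ns)) {
    sc <- annot$sift_score[ns]
    if (any(is.na(sc)))
      stop("nonsynonymous site without a SIFT score")
    if (any(sc < 0 | sc > 1))
      stop("SIFT score outside [0, 1]")
  }
  annot$class <- ifelse(annot$consequence == "synonymous", "synonymous",
                 ifelse(!ns, "other",
                 ifelse(annot$sift_score < threshold,
                        "nonsyn_not_tolerated", "nonsyn_tolerated")))
  annot
}

#' Full shared/private partition table stratified by consequence class
#'
#' Applies the fixed-difference and minor-allele-count filters, partitions
#' the surviving sites by island, and cross-tabulates the categories
#' against consequence classes: the cohort-wide accounting of how much
#' variation is shared between the islands and how much is private, overall
#' and among synonymous / tolerated / not-tolerated coding variants.
#'
#' @param x a \code{\link{variant_table}}
#' @param island_map named sample-to-island vector
#'   (see \code{\link{partition_by_island}})
#' @param annot optional annotation data.frame
#'   (see \code{\link{classify_sift}}); unannotated sites count only in the
#'   \code{all} row
#' @param mac minimum minor allele count (default 2)
#' @param sift_threshold SIFT cutoff (default 0.05)
#' @return list with \code{table}: data.frame of counts, one row per class
#'   (\code{all} first) and one column per category plus \code{total}; and
#'   \code{variants}: the filtered \code{variant_table}
#' @export
partition_table <- function(x, island_map, annot = NULL, mac = 2L,
                            sift_threshold = 0.05) {
  x <- mac_filter(remove_fixed_differences(x), min_count = mac)
  part <- partition_by_island(x, island_map)
  levs <- levels(part$category)
  tab_row <- function(cat_subset) {
    cnt <- table(factor(cat_subset, levels = levs))
    stats::setNames(as.integer(cnt), levs)
  }
  rows <- list(all = tab_row(part$category))
  if (!is.null(annot)) {
    annot <- classify_sift(annot, threshold = sift_threshold)
    k <- match(paste(x$sites$chrom, x$sites$pos),
               paste(annot$chrom, annot$pos))
    cls <- annot$class[k]
    for (cl in c("synonymous", "nonsyn_tolerated", "nonsyn_not_tolerated"))
      rows[[cl]] <- tab_row(part$category[!is.na(cls) & cls == cl])
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab$total <- rowSums(tab)
  tab <- cbind(data.frame(class = names(rows), stringsAsFactors = FALSE),
               tab)
  rownames(tab) <- NULL
  list(table = tab, variants = x, category = part$category)
}

#' Heterozygous/homozygous genotype ratio per consequence class
#'
#' The ratio of heterozygous to homozygous-alternate genotype observations
#' across all samples and sites of a class. Among damaging variants, an
#' excess of heterozygotes over homozygotes is a signature of purging:
#' selection removes the allele when exposed in homozygous state.
#'
#' @param x a \code{\link{variant_table}}
#' @param class_of_site vector (length \code{n_sites(x)}) assigning each
#'   site to a class; \code{NA} sites are skipped
#' @return data.frame per class: \code{class}, \code{n_het}, \code{n_hom},
#'   \code{ratio} (NA with a \code{defined = FALSE} flag when there are no
#'   homozygous-alternate observations)
#' @export
het_hom_ratio <- function(x, class_of_site) {
  stopifnot(length(class_of_site) == n_sites(x))
  classes <- unique(class_of_site[!is.na(class_of_site)])
  res <- lapply(classes, function(cl) {
    rows <- which(!is.na(class_of_site) & class_of_site == cl)
    g <- x$gt[rows, , drop = FALSE]
    n_het <- sum(g == 1L, na.rm = TRUE)
    n_hom <- sum(g == 2L, na.rm = TRUE)
    data.frame(class = cl, n_het = n_het, n_hom = n_hom,
               ratio = if (n_hom > 0) n_het / n_hom else NA_real_,
               defined = n_hom > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
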