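#' Default pipeline parameters
#'
#' The published analysis settings: 10-kb bins, ROHs of at least 20
#' consecutive bins below 0.33 of the genomic average, per-sample depth
#' window 0.5--2.0x the mean, at least 1,000 covered sites per bin, minor
#' allele count 2, sex chromosomes X and Y excluded, ROH length categories
#' at 0.2/0.5/1/2/5 Mb, SIFT threshold 0.05.
#'
#' @return named list of parameter defaults
#' @export
pipeline_defaults <- function() {
  list(bin_size = 10000L, min_bins = 20L, frac = 0.33,
       depth_lower = 0.5, depth_upper = 2.0, min_covered = 1000L,
       mac = 2L, sex_chroms = c("X", "Y"),
       category_edges = c(0.2, 0.5, 1, 2, 5) * 1e6,
       sift_threshold = 0.05, max_gap_bins = 0L, seed = 1L)
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates filter -> bin -> ROH -> diversity -> partition -> tree ->
#' pedigree from a single configuration (a list, or a path to a YAML file
#' with the same fields) and writes the paper-style outputs. Every stage is
#' driven by the package functions, so an identical configuration
#' reproduces an identical bundle. Stages whose inputs are absent are
#' skipped.
#'
#' Configuration fields: \code{vcf} (path) or \code{variants} (a
#' \code{\link{variant_table}}); \code{chrom_lengths} (named list, enables
#' the ROH stage); \code{coverage} (named per-sample list of per-bin
#' coverage data.frames, a single data.frame with a \code{sample} column,
#' or a path to such a TSV); \code{island_map} (named list, enables the
#' partition stage); \code{annotation} (path to a consequence/SIFT TSV);
#' \code{studbook} (path, enables the pedigree stage); \code{out_dir};
#' plus any of the parameters in \code{\link{pipeline_defaults}}.
#'
#' @param config list or YAML path
#' @return (invisibly) list with elements \code{summary}, \code{rohs},
#'   \code{partition}, \code{tree}, \code{pedigree_F},
#'   \code{generation_time}, \code{params} — those produced by the enabled
#'   stages
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(pipeline_defaults(),
                              config[names(config) %in%
                                     names(pipeline_defaults())])
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  log_lines <- c(sprintf("rohdiv pipeline run"),
                 vapply(names(params), function(p)
                   sprintf("param %s = %s", p,
                           paste(params[[p]], collapse = ",")),
                   character(1)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(params = params)

  x <- stage("input", {
    if (!is.null(config$variants)) config$variants
    else if (!is.null(config$vcf)) read_vcf(config$vcf)
    else stop("config needs 'vcf' or 'variants'")
  })
  x <- stage("depth_filter",
             filter_depth(x, lower = params$depth_lower,
                          upper = params$depth_upper))
  x <- stage("biallelic", select_biallelic(x))

  if (!is.null(config$chrom_lengths)) {
    chrom_lengths <- unlist(config$chrom_lengths)
    coverage <- config$coverage
    if (is.character(coverage))
      coverage <- utils::read.delim(coverage, stringsAsFactors = FALSE)
    cov_for <- function(s) {
      if (is.null(coverage)) NULL
      else if (is.data.frame(coverage) && "sample" %in% names(coverage))
        coverage[coverage$sample == s, , drop = FALSE]
      else if (is.data.frame(coverage)) coverage
      else coverage[[s]]
    }
    summaries <- list(); all_rohs <- list()
    for (s in samples(x)) {
      stage(paste0("roh:", s), {
        track <- bin_genome(x, s, chrom_lengths, coverage = cov_for(s),
                            bin_size = params$bin_size)
        track <- filter_bins(scale_bins(track),
                             sex_chroms = params$sex_chroms,
                             min_covered = params$min_covered)
        rohs <- call_rohs(track, min_bins = params$min_bins,
                          frac = params$frac,
                          max_gap_bins = params$max_gap_bins)
        summaries[[s]] <- cbind(data.frame(sample = s),
                                 roh_summary(track, rohs,
                                             edges = params$category_edges))
        if (nrow(rohs) > 0) all_rohs[[s]] <- cbind(sample = s, rohs)
      })
    }
    res$summary <- do.call(rbind, summaries)
    rownames(res$summary) <- NULL
    res$rohs <- if (length(all_rohs)) do.call(rbind, all_rohs)
                else data.frame()
    emit("sample_summary.tsv", function(p)
      utils::write.table(res$summary, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
    emit("rohs.bed", function(p) {
      bed <- res$rohs
      if (nrow(bed) > 0)
        bed <- bed[, c("chrom", "start", "end", "sample", "n_bins")]
      utils::write.table(bed, p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    })
  }

  if (!is.null(config$island_map)) {
    island_map <- unlist(config$island_map)
    annot <- if (!is.null(config$annotation))
      utils::read.delim(config$annotation, stringsAsFactors = FALSE)
    part <- stage("partition",
                  partition_table(x, island_map, annot = annot,
                                  mac = params$mac,
                                  sift_threshold = params$sift_threshold))
    res$partition <- part$table
    emit("partition.tsv", function(p)
      utils::write.table(part$table, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  if (length(samples(x)) >= 3) {
    stage("tree", {
      dm <- allele_sharing_distance(x)
      tree <- midpoint_root(neighbor_joining(dm$dist))
      res$tree <- tree
      emit("tree.nwk", function(p) ape::write.tree(tree, file = p))
      emit("distances.tsv", function(p)
        utils::write.table(dm$dist, p, sep = "\t", quote = FALSE))
    })
  }

  if (!is.null(config$studbook)) {
    stage("pedigree", {
      ped <- read_studbook(config$studbook)
      res$pedigree_F <- inbreeding(ped)
      res$generation_time <- tryCatch(generation_time(ped),
                                       error = function(e) NA_real_)
      emit("inbreeding.tsv", function(p)
        utils::write.table(
          data.frame(id = names(res$pedigree_F), F = res$pedigree_F),
          p, sep = "\t", quote = FALSE, row.names = FALSE))
    })
  }

  emit("pipeline.log", function(p) writeLines(log_lines, p))
  invisible(res)
}
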