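
#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with validation; round-trips
#' losslessly through a flat `key = value` text file so runs are easy to
#' reproduce and diff.
#'
#' @param bin_size bin width, nt (default 50)
#' @param min_ip minimum mean raw IP count per bin (default 15)
#' @param min_enrichment minimum mean fold enrichment (default 1)
#' @param top_frac fraction of top bins for the IP size factor (default 0.01)
#' @param fdr_cutoff BH cutoff for reporting peaks (default 0.1)
#' @param strandness `"none"`, `"forward"` or `"reverse"`
#' @param paired_end collapse mate pairs into fragments
#' @param min_mapq mapping-quality floor
#' @param tol,max_iter optimizer controls
#' @param keep_nonconverged include non-converged bins in BH
#' @param seed seed for any stochastic step
#' @return validated list of class `merip_config`
#' @export
merip_config <- function(bin_size = 50, min_ip = 15, min_enrichment = 1,
                         top_frac = 0.01, fdr_cutoff = 0.1,
                         strandness = "none", paired_end = FALSE,
                         min_mapq = 0, tol = 1e-8, max_iter = 1000,
                         keep_nonconverged = FALSE, seed = 1) {
  stopifnot(bin_size >= 10, min_ip >= 0, min_enrichment >= 0,
            top_frac > 0, top_frac <= 0.1, fdr_cutoff > 0, fdr_cutoff < 1,
            strandness %in% c("none", "forward", "reverse"),
            is.logical(paired_end), min_mapq >= 0, tol > 0, max_iter >= 1)
  structure(as.list(environment()), class = "merip_config")
}

#' Write a configuration as flat key = value text
#' @param config a `merip_config`
#' @param path output file
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", format(config[[k]], digits = 17))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path config file
#' @return a `merip_config`
#' @export
read_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    if (is.integer(v)) v <- as.numeric(v)  # numbers are doubles throughout
    v
  })
  names(vals) <- vapply(kv, `[[`, "", 1)
  do.call(merip_config, vals)
}

#' Run the pipeline end to end
#'
#' Thin orchestration over the stage functions: count -> normalize ->
#' filter -> test -> report. Per-stage bin/gene tallies are logged to
#' stderr and a JSON run manifest is written beside the outputs.
#'
#' @param sample_sheet tibble (or TSV path) with `sample`, `input_bam`,
#'   `ip_bam`, `group` and optional covariate columns
#' @param gtf gene annotation GTF path
#' @param out_dir output directory (created if absent)
#' @param config a [merip_config()]
#' @return list with `dm` (the `merip_dm` table), `peaks`, and output paths,
#'   invisibly
#' @export
run_pipeline <- function(sample_sheet, gtf, out_dir, config = merip_config()) {
  if (is.character(sample_sheet))
    sample_sheet <- as_tibble(read.table(sample_sheet, header = TRUE,
                                         sep = "\t", stringsAsFactors = FALSE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[meripdm] ", ...)

  log_stage("building gene models from ", gtf)
  models <- build_gene_models(gtf, bin_size = config$bin_size)
  log_stage(nrow(models), " genes, ", sum(models$n_bins), " bins")

  counts <- count_bins(sample_sheet, models, paired_end = config$paired_end,
                       strandness = config$strandness,
                       min_mapq = config$min_mapq)
  log_stage("counted ", nrow(counts), " bins x ", nrow(sample_sheet),
            " samples")
  norm <- normalize_merip(counts, top_frac = config$top_frac)
  mask <- filter_bins(norm, min_ip = config$min_ip,
                      min_enrichment = config$min_enrichment)
  log_stage(sum(mask$keep), " bins retained after filtering")

  design <- sample_sheet[setdiff(names(sample_sheet),
                                 c("input_bam", "ip_bam"))]
  dm <- dm_test(norm, design, mask = mask,
                keep_nonconverged = config$keep_nonconverged,
                tol = config$tol, max_iter = config$max_iter)
  log_stage(sum(!is.na(dm$padj) & dm$padj < config$fdr_cutoff),
            " significant bins at FDR ", config$fdr_cutoff)
  peaks <- merge_significant_bins(dm, fdr_cutoff = config$fdr_cutoff)

  paths <- list(
    counts = file.path(out_dir, "bin_counts.tsv"),
    dm = file.path(out_dir, "dm_results.tsv"),
    peaks = file.path(out_dir, "peaks.bed"),
    peak_stats = file.path(out_dir, "peak_stats.tsv"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  write_tsv_plain(counts, paths$counts)
  write_tsv_plain(dm, paths$dm)
  if (nrow(peaks)) write_bed12(peaks, models, paths$peaks)
  write_tsv_plain(peaks, paths$peak_stats)
  manifest <- list(config = unclass(config),
                   n_genes = nrow(models), n_bins = nrow(counts),
                   n_tested = nrow(dm), n_peaks = nrow(peaks))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paths$manifest)
  invisible(list(dm = dm, peaks = peaks, models = models, norm = norm,
                 paths = paths))
}

write_tsv_plain <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}
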