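
#' Merge adjacent significant bins into peaks
#'
#' Bins with `padj < fdr_cutoff` and consecutive bin indices within the same
#' gene become one peak. The peak log fold change is the inverse-variance
#' weighted mean of member estimates; the peak score is the minimum padj.
#' Bins of different genes are never merged, even if genomically adjacent.
#'
#' @param results a `merip_dm` tibble from [dm_test()]
#' @param fdr_cutoff BH-adjusted significance cutoff (default 0.1)
#' @return `merip_peaks` tibble: `gene_id`, `peak_id`, `tx_start`, `tx_end`,
#'   `n_bins`, `lfc`, `padj` (min over members); empty when nothing is
#'   significant
#' @export
merge_significant_bins <- function(results, fdr_cutoff = 0.1) {
  sig <- filter(results, !is.na(.data$padj) & .data$padj < fdr_cutoff)
  if (!nrow(sig)) {
    out <- tibble(gene_id = character(), peak_id = character(),
                  tx_start = integer(), tx_end = integer(),
                  n_bins = integer(), lfc = numeric(), padj = numeric())
    class(out) <- c("merip_peaks", class(out))
    return(out)
  }
  out <- sig |>
    arrange(.data$gene_id, .data$bin_index) |>
    group_by(.data$gene_id) |>
    mutate(run = cumsum(c(1L, diff(.data$bin_index) != 1L))) |>
    group_by(.data$gene_id, .data$run) |>
    summarise(
      tx_start = min(.data$tx_start),
      tx_end = max(.data$tx_end),
      n_bins = n(),
      lfc = ivw_mean(.data$lfc, .data$se),
      padj = min(.data$padj),
      .groups = "drop"
    ) |>
    mutate(peak_id = paste0(.data$gene_id, ":", .data$run)) |>
    select("gene_id", "peak_id", "tx_start", "tx_end", "n_bins", "lfc", "padj")
  class(out) <- c("merip_peaks", class(out))
  out
}

# inverse-variance weighted mean; falls back to plain mean without finite se
ivw_mean <- function(x, se) {
  w <- 1 / se^2
  ok <- is.finite(w) & w > 0
  if (!any(ok)) return(mean(x))
  sum(x[ok] * w[ok]) / sum(w[ok])
}

#' Convert peaks to BED12 records
#'
#' Maps each peak's transcript interval back to genome coordinates through
#' its gene model; intron-spanning peaks become multi-block records. All
#' coordinates are 0-based half-open per the BED convention. The score
#' column is `min(1000, round(-10 log10(padj)))`; thickStart/thickEnd mirror
#' the peak bounds (no CDS semantics).
#'
#' @param peaks a `merip_peaks` tibble
#' @param models gene models from [build_gene_models()]
#' @return tibble with the 12 BED columns (chrom, chromStart, chromEnd,
#'   name, score, strand, thickStart, thickEnd, itemRgb, blockCount,
#'   blockSizes, blockStarts)
#' @export
to_bed12 <- function(peaks, models) {
  purrr::pmap_dfr(peaks[c("gene_id", "peak_id", "tx_start", "tx_end", "padj")],
    function(gene_id, peak_id, tx_start, tx_end, padj) {
      i <- match(gene_id, models$gene_id)
      if (is.na(i)) stop("peak references gene absent from models: ", gene_id)
      if (tx_end > models$tx_length[i] || tx_start < 0)
        stop("peak outside gene model bounds for ", gene_id)
      blocks <- tx_blocks(models$exons[[i]], tx_start, tx_end)
      tibble(
        chrom = models$chrom[i],
        chromStart = blocks$start[1],
        chromEnd = blocks$end[nrow(blocks)],
        name = peak_id,
        score = min(1000, round(-10 * log10(padj))),
        strand = models$strand[i],
        thickStart = blocks$start[1],
        thickEnd = blocks$end[nrow(blocks)],
        itemRgb = "0",
        blockCount = nrow(blocks),
        blockSizes = paste0(blocks$end - blocks$start, collapse = ","),
        blockStarts = paste0(blocks$start - blocks$start[1], collapse = ",")
      )
    })
}

# genome blocks (0-based half-open, sorted, disjoint) covered by a
# transcript interval [tx_start, tx_end)
tx_blocks <- function(exons, tx_start, tx_end) {
  w <- exons$end - exons$start
  cum <- cumsum(c(0L, w))
  n <- nrow(exons)
  out <- NULL
  for (k in seq_len(n)) {
    lo <- max(tx_start, cum[k]); hi <- min(tx_end, cum[k + 1])
    if (lo < hi) {
      out <- bind_rows(out, tibble(start = exons$start[k] + (lo - cum[k]),
                                   end = exons$start[k] + (hi - cum[k])))
    }
  }
  out
}

#' Write peaks as a BED12 file
#'
#' @inheritParams to_bed12
#' @param path output file (tab-separated, no header)
#' @return the BED12 tibble, invisibly
#' @export
write_bed12 <- function(peaks, models, path) {
  bed <- to_bed12(peaks, models)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bed)
}

#' Read a BED12 file back into a tibble
#' @param path BED12 file as written by [write_bed12()]
#' @return tibble with the 12 BED columns
#' @export
read_bed12 <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
                 "thickStart", "thickEnd", "itemRgb", "blockCount",
                 "blockSizes", "blockStarts")
  as_tibble(df)
}
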