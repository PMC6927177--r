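
#' Build exon-union gene models with a fixed-width bin grid
#'
#' Exons of each gene are unioned (overlapping records merged) and
#' concatenated in genome order to form one transcript per gene; the
#' concatenated transcript is tiled with bins of `bin_size` nt (the last bin
#' of a gene may be shorter; a gene shorter than `bin_size` yields a single
#' bin). Transcript coordinates are 0-based half-open throughout.
#'
#' @param gtf path to a GTF file (ensembl/gencode dialect) with `exon`
#'   features carrying a `gene_id` attribute
#' @param bin_size bin width in nt (>= 10); 50 suits libraries of >= 20M
#'   mappable reads, 100 is recommended below ~15M
#' @return a tibble of class `merip_gene_models`, one row per gene, with
#'   columns `gene_id`, `chrom`, `strand`, `tx_length`, `n_bins`, `bin_size`
#'   and a list-column `exons` of tibbles with 0-based half-open
#'   `start`/`end`; genes whose exon records span several chromosomes or
#'   strands are skipped with a warning
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "meripdm")
#' build_gene_models(gtf, bin_size = 50)
#' @export
build_gene_models <- function(gtf, bin_size = 50) {
  if (bin_size < 10) stop("bin_size must be >= 10 nt")
  gr <- tryCatch(
    rtracklayer::import(gtf, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", gtf, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", gtf)
  if (is.null(gr$gene_id)) stop("GTF exons carry no gene_id attribute")

  exdf <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom   = as.character(GenomicRanges::seqnames(gr)),
    strand  = as.character(GenomicRanges::strand(gr)),
    start   = GenomicRanges::start(gr) - 1L,  # GTF 1-based incl -> 0-based half-open
    end     = GenomicRanges::end(gr)
  )
  spans <- exdf |>
    distinct(.data$gene_id, .data$chrom, .data$strand) |>
    count(.data$gene_id)
  bad <- spans$gene_id[spans$n > 1]
  if (length(bad)) {
    warning("skipping ", length(bad),
            " gene(s) spanning multiple chromosomes or strands: ",
            paste(head(bad, 5), collapse = ", "))
    exdf <- filter(exdf, !.data$gene_id %in% bad)
  }
  if (!nrow(exdf)) stop("no usable genes in ", gtf)

  models <- exdf |>
    group_by(.data$gene_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      chrom  = first(.data$chrom),
      strand = first(.data$strand),
      exons  = list(merge_intervals(.data$start, .data$end)),
      .groups = "drop"
    ) |>
    mutate(
      tx_length = vapply(.data$exons, function(e) sum(e$end - e$start), 0L),
      bin_size  = as.integer(bin_size),
      n_bins    = pmax(1L, as.integer(ceiling(.data$tx_length / bin_size)))
    )
  class(models) <- c("merip_gene_models", class(models))
  models
}

# union of possibly-overlapping sorted intervals (0-based half-open)
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  tibble(start = as.integer(c(out_s, ms)), end = as.integer(c(out_e, me)))
}

#' The bin grid of a set of gene models
#'
#' @param models a `merip_gene_models` tibble
#' @return tibble with `gene_id`, `bin_index` (0-based), and 0-based
#'   half-open transcript coordinates `tx_start`, `tx_end`
#' @export
bin_grid <- function(models) {
  purrr::pmap_dfr(
    models[c("gene_id", "tx_length", "bin_size", "n_bins")],
    function(gene_id, tx_length, bin_size, n_bins) {
      s <- seq.int(0L, by = bin_size, length.out = n_bins)
      tibble(gene_id = gene_id, bin_index = seq_len(n_bins) - 1L,
             tx_start = s, tx_end = pmin(s + bin_size, tx_length))
    }
  )
}

gene_exons <- function(models, gene_id) {
  i <- match(gene_id, models$gene_id)
  if (is.na(i)) stop("gene '", gene_id, "' not in gene models")
  models$exons[[i]]
}

#' Map transcript offsets to genome positions
#'
#' The transcript coordinate of a gene runs over its concatenated exon union
#' in genome order; both coordinate systems are 0-based.
#'
#' @param models a `merip_gene_models` tibble
#' @param gene_id single gene identifier
#' @param offsets integer vector of transcript offsets in `[0, tx_length)`
#' @return integer vector of genome positions (0-based)
#' @export
tx_to_genome <- function(models, gene_id, offsets) {
  ex <- gene_exons(models, gene_id)
  w <- ex$end - ex$start
  cum <- cumsum(c(0L, w))
  if (any(offsets < 0 | offsets >= cum[length(cum)]))
    stop("transcript offset out of range for gene ", gene_id)
  k <- findInterval(offsets, cum, rightmost.closed = FALSE)
  ex$start[k] + (offsets - cum[k])
}

#' Map genome positions to transcript offsets
#'
#' @inheritParams tx_to_genome
#' @param pos integer vector of genome positions (0-based); positions outside
#'   the exon union map to `NA`
#' @return integer vector of transcript offsets (`NA` for intronic/outside)
#' @export
genome_to_tx <- function(models, gene_id, pos) {
  ex <- gene_exons(models, gene_id)
  w <- ex$end - ex$start
  cum <- cumsum(c(0L, w))
  k <- findInterval(pos, ex$start)
  ok <- k >= 1 & pos < ex$end[pmax(k, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- cum[k[ok]] + (pos[ok] - ex$start[k[ok]])
  out
}
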