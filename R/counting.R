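
#' Count INPUT and IP fragments per transcript bin
#'
#' Each aligned fragment (a single-end read, or a properly-paired mate pair
#' collapsed to its leftmost-start/rightmost-end span) is assigned to the one
#' bin containing its fragment midpoint in transcript coordinates; fragments
#' whose span does not touch the exon union of a gene are not counted for
#' that gene. Junction-spanning fragments are clipped to the exon union
#' before the midpoint is taken, so every counted fragment contributes
#' exactly once within a gene.
#'
#' @param samples sample sheet tibble with columns `sample`, `input_bam`,
#'   `ip_bam` (BAM with index, or plain-text SAM which is converted on the
#'   fly); extra columns (group, covariates) are carried along by downstream
#'   helpers, not used here
#' @param models gene models from [build_gene_models()]
#' @param paired_end collapse properly-paired mates into one fragment
#' @param strandness `"none"` (default, unstranded), `"forward"` (read strand
#'   must match gene strand) or `"reverse"`
#' @param min_mapq drop alignments below this mapping quality (default 0);
#'   secondary and supplementary alignments are always dropped
#' @return a `merip_counts` tibble: bin key columns plus `input_<sample>` and
#'   `ip_<sample>` integer columns, one row per bin of every gene model
#' @export
count_bins <- function(samples, models, paired_end = FALSE,
                       strandness = c("none", "forward", "reverse"),
                       min_mapq = 0) {
  strandness <- match.arg(strandness)
  stopifnot(all(c("sample", "input_bam", "ip_bam") %in% names(samples)))
  grid <- bin_grid(models)
  exons <- exon_index(models)
  count1 <- function(path, sample) {
    n <- count_one_library(path, sample, models, exons, grid,
                           paired_end, strandness, min_mapq)
    n
  }
  input <- mapply(count1, samples$input_bam, samples$sample)
  ip    <- mapply(count1, samples$ip_bam, samples$sample)
  colnames(input) <- colnames(ip) <- samples$sample
  new_counts_tbl(grid, input = input, ip = ip)
}

# flat exon table with per-exon cumulative transcript offsets
exon_index <- function(models) {
  ex <- purrr::map2_dfr(models$gene_id, models$exons, function(g, e) {
    w <- e$end - e$start
    tibble(gene_id = g, start = e$start, end = e$end,
           cum = cumsum(c(0L, w))[seq_along(w)])
  })
  i <- match(ex$gene_id, models$gene_id)
  ex$chrom <- models$chrom[i]
  ex$gene_strand <- models$strand[i]
  ex
}

ensure_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("missing index for ", path, "; run samtools index first")
  }
  path
}

count_one_library <- function(path, sample, models, exons, grid,
                              paired_end, strandness, min_mapq) {
  bam <- ensure_bam(path)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  what <- c("flag", "rname", "strand", "pos", "mapq", "cigar", "isize")
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(flag = flag,
                                                               what = what))[[1]]
  if (!length(b$pos) || all(is.na(b$pos)))
    stop("zero mapped reads in library of sample '", sample, "' (", path, ")")
  mapq <- ifelse(is.na(b$mapq), 255L, b$mapq)
  keep <- mapq >= min_mapq & !is.na(b$pos)
  frag <- tibble(
    chrom = as.character(b$rname)[keep],
    strand = as.character(b$strand)[keep],
    pos0 = b$pos[keep] - 1L,                       # SAM 1-based -> 0-based
    width = cigar_ref_width(b$cigar[keep]),
    flag = b$flag[keep],
    isize = b$isize[keep]
  )
  if (paired_end) {
    proper <- !is.na(frag$isize) & bitwAnd(frag$flag, 2L) > 0L & frag$isize != 0L
    # leftmost mate carries isize > 0; count the pair once through it
    lead <- proper & frag$isize > 0L
    single <- !proper
    frag <- bind_rows(
      mutate(frag[lead, ], width = .data$isize),
      frag[single, ]
    )
  }
  frag$end0 <- frag$pos0 + frag$width
  frag$id <- seq_len(nrow(frag))

  hits <- overlap_exons(frag, exons)
  if (strandness == "forward") hits <- filter(hits, .data$strand == .data$gene_strand)
  if (strandness == "reverse") hits <- filter(hits, .data$strand != .data$gene_strand)
  if (!nrow(hits)) return(integer(nrow(grid)))

  # transcript span of the exon-clipped fragment, then midpoint -> bin
  mids <- hits |>
    mutate(
      lo = .data$cum + (pmax(.data$pos0, .data$start) - .data$start),
      hi = .data$cum + (pmin(.data$end0, .data$end) - .data$start) - 1L
    ) |>
    group_by(.data$id, .data$gene_id) |>
    summarise(lo = min(.data$lo), hi = max(.data$hi), .groups = "drop") |>
    mutate(mid = (.data$lo + .data$hi) %/% 2L)

  bs <- models$bin_size[1]
  tally <- mids |>
    mutate(bin_index = .data$mid %/% bs) |>
    count(.data$gene_id, .data$bin_index)
  out <- grid |>
    left_join(tally, by = c("gene_id", "bin_index")) |>
    mutate(n = if_else(is.na(.data$n), 0L, .data$n))
  out$n
}

# reference-consumed width of a CIGAR string (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    sum(n[grepl("[MDN=X]", ops)])
  }, 0L)
}

# fragment x exon overlap join via GRanges
overlap_exons <- function(frag, exons) {
  fr <- GenomicRanges::GRanges(frag$chrom,
                               IRanges::IRanges(frag$pos0 + 1L, frag$end0))
  exr <- GenomicRanges::GRanges(exons$chrom,
                                IRanges::IRanges(exons$start + 1L, exons$end))
  ov <- GenomicRanges::findOverlaps(fr, exr, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  bind_cols(
    frag[qi, c("id", "pos0", "end0", "strand")],
    exons[si, c("gene_id", "start", "end", "cum", "gene_strand")]
  )
}

#' Gene-level INPUT counts (geneSum)
#'
#' Sums bin-level INPUT counts within each gene; a robust measurement of the
#' pre-IP RNA expression level.
#'
#' @param counts a `merip_counts` tibble
#' @return tibble with `gene_id` and one `input_<sample>` column per sample
#' @export
gene_sum <- function(counts) {
  stopifnot(nrow(counts) > 0)
  counts |>
    select("gene_id", dplyr::starts_with("input_")) |>
    group_by(.data$gene_id) |>
    summarise(across(dplyr::everything(), sum), .groups = "drop")
}
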