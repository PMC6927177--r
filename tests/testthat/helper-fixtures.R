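# Programmatic fixtures: tiny GTFs and SAM files written to tempdir at test
# time, plus an independent brute-force midpoint-tally oracle that parses
# SAM text directly (no package code).

`%||%` <- function(a, b) if (is.null(a)) b else a

# exons: tibble(gene_id, chrom, strand, start, end) with 0-based half-open
# coordinates; written as 1-based inclusive GTF exon records
write_toy_gtf <- function(exons, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$gene_id
  )
  writeLines(lines, path)
  path
}

toy_exons <- function() {
  tibble::tibble(
    gene_id = c("gA", "gA", "gB"),
    chrom = c("chr1", "chr1", "chr1"),
    strand = c("+", "+", "-"),
    start = c(100L, 300L, 1000L),
    end = c(200L, 400L, 1150L)
  )
}

# reads: tibble(pos0, cigar, flag); written as single-end SAM over chr1
write_sam <- function(reads, path = tempfile(fileext = ".sam"),
                      chrom = "chr1", chrom_len = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  reads <- reads[order(reads$pos0), ]
  flag <- if ("flag" %in% names(reads)) reads$flag else 0L
  mapq <- if ("mapq" %in% names(reads)) reads$mapq else 60L
  body <- sprintf("r%04d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                  seq_len(nrow(reads)), flag, chrom,
                  reads$pos0 + 1L, mapq, reads$cigar)
  writeLines(c(hdr, body), path)
  path
}

sam_cols <- function(reads, col, default) {
  if (col %in% names(reads)) reads[[col]] else rep(default, nrow(reads))
}

# Independent oracle: per gene, enumerate the transcript offsets covered by
# each read's reference span, take the midpoint of min/max offsets, tally
# per bin. Deliberately naive (explicit offset enumeration).
oracle_midpoint_tally <- function(sam_path, exons, bin_size) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  genes <- split(exons, exons$gene_id)
  tally <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next
    pos0 <- as.integer(f[4]) - 1L
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("[0-9]+", "", ops)
    len <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    s <- pos0; e <- pos0 + len
    for (g in genes) {
      g <- g[order(g$start), ]
      offs <- integer(0); cum <- 0L
      for (k in seq_len(nrow(g))) {
        lo <- max(s, g$start[k]); hi <- min(e, g$end[k])
        if (lo < hi) offs <- c(offs, (cum + lo - g$start[k]):(cum + hi - g$start[k] - 1L))
        cum <- cum + g$end[k] - g$start[k]
      }
      if (length(offs)) {
        mid <- (min(offs) + max(offs)) %/% 2L
        key <- paste(g$gene_id[1], mid %/% bin_size)
        tally[[key]] <- (tally[[key]] %||% 0L) + 1L
      }
    }
  }
  tally
}

# random uniform single-end reads over given exons, length read_len
random_reads <- function(n, exons, read_len = 30L, seed = 1) {
  set.seed(seed)
  pick <- sample(nrow(exons), n, replace = TRUE)
  pos0 <- mapply(function(i) {
    rng <- seq(exons$start[i], max(exons$start[i], exons$end[i] - read_len))
    rng[sample.int(length(rng), 1)]
  }, pick)
  tibble::tibble(pos0 = as.integer(pos0),
                 cigar = sprintf("%dM", read_len),
                 flag = 0L, mapq = 60L)
}

# small simulated dataset reused across tests
quick_sim <- function(n_bins = 1500, beta0 = 1, seed = 42, ...) {
  simulate_pois_gamma(n_bins = n_bins, beta0 = beta0, seed = seed, ...)
}
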