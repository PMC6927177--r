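
# Bin-count tables travel as wide tibbles: key columns
# (gene_id, bin_index, tx_start, tx_end) then one column per sample per
# channel, named input_<sample> / ip_<sample>.

KEY_COLS <- c("gene_id", "bin_index", "tx_start", "tx_end")

#' Sample names stored in a bin-count table
#' @param counts a bin-count tibble from [count_bins()] or [simulate_pois_gamma()]
#' @return character vector of sample names
#' @export
count_samples <- function(counts) {
  sub("^input_", "", grep("^input_", names(counts), value = TRUE))
}

#' Extract one channel of a bin-count table as a numeric matrix
#'
#' @param counts a bin-count tibble
#' @param channel `"input"` or `"ip"`
#' @return bins x samples matrix, columns named by sample
#' @export
count_matrix <- function(counts, channel = c("input", "ip")) {
  channel <- match.arg(channel)
  cols <- grep(paste0("^", channel, "_"), names(counts), value = TRUE)
  if (!length(cols)) stop("no '", channel, "_*' columns found")
  m <- as.matrix(counts[cols])
  colnames(m) <- sub(paste0("^", channel, "_"), "", cols)
  m
}

bin_keys <- function(counts) counts[intersect(KEY_COLS, names(counts))]

new_counts_tbl <- function(keys, input = NULL, ip = NULL) {
  out <- as_tibble(keys)
  if (!is.null(input)) {
    colnames(input) <- paste0("input_", colnames(input))
    out <- bind_cols(out, as_tibble(input))
  }
  if (!is.null(ip)) {
    colnames(ip) <- paste0("ip_", colnames(ip))
    out <- bind_cols(out, as_tibble(ip))
  }
  class(out) <- c("merip_counts", class(out))
  out
}

#' @importFrom dplyr bind_cols bind_rows group_by summarise mutate filter
#'   arrange select distinct count first across all_of left_join inner_join
#'   ungroup n lag pull rename row_number desc if_else
NULL
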