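
#' Median-of-ratios size factors for INPUT libraries
#'
#' The INPUT library is an ordinary RNA-seq library, so sample depth is
#' estimated by the median-of-ratios method on gene-level counts: the
#' reference for each gene is the geometric mean of its counts across
#' samples (genes with a zero anywhere are excluded), and a sample's factor
#' is the median ratio of its counts to the reference. Robust to a handful
#' of highly expressed genes, unlike total-count scaling.
#'
#' @param genes gene-level count tibble from [gene_sum()] (columns `gene_id`
#'   + `input_<sample>`), or a plain numeric matrix genes x samples
#' @return tibble with `sample` and `size_factor`; attribute
#'   `"norm_gene_counts"` holds the per-column normalized gene count matrix
#' @export
input_size_factors <- function(genes) {
  m <- if (is.matrix(genes)) genes else count_matrix(genes, "input")
  if (ncol(m) < 2) stop("need >= 2 samples for median-of-ratios")
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no gene has positive counts in every sample; sequence deeper ",
         "or merge genes")
  ref <- exp(rowMeans(log(m[pos, , drop = FALSE])))
  sf <- apply(m[pos, , drop = FALSE] / ref, 2, median)
  out <- tibble(sample = colnames(m), size_factor = unname(sf))
  attr(out, "norm_gene_counts") <- sweep(m, 2, sf, "/")
  out
}

#' IP size factors from top-bin fold enrichment
#'
#' IP depth depends on both sequencing depth and antibody pull-down
#' efficiency, so it is estimated from the fold enrichment
#' E = IP bin count / normalized gene-level INPUT count, averaged over the
#' most enriched bins only (regions where IP counts reflect genuine binding
#' rather than background). Bins are ranked by mean raw IP count across
#' samples; per-sample factors are rescaled to geometric mean 1.
#'
#' @param counts a `merip_counts` tibble
#' @param norm_genes normalized gene count matrix (genes x samples, rownames
#'   gene_id), e.g. `attr(input_size_factors(gene_sum(counts)), "norm_gene_counts")`
#' @param top_frac fraction of bins used (default 0.01, i.e. the top 1%);
#'   must be in (0, 0.1]
#' @param summary `"mean"` (default) or `"median"` of E over the top bins
#' @return tibble with `sample` and `size_factor` (geometric mean 1)
#' @export
ip_size_factors <- function(counts, norm_genes, top_frac = 0.01,
                            summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (top_frac <= 0 || top_frac > 0.1) stop("top_frac must be in (0, 0.1]")
  ip <- count_matrix(counts, "ip")
  n_top <- max(ceiling(top_frac * nrow(ip)), 10L)
  if (n_top > nrow(ip))
    stop("fewer than 10 top bins available; ",
         "too few enriched bins to estimate IP efficiency")
  top <- order(rowMeans(ip), decreasing = TRUE)[seq_len(n_top)]
  s <- norm_genes[match(counts$gene_id[top], rownames(norm_genes)), , drop = FALSE]
  E <- ip[top, , drop = FALSE] / s
  E[!is.finite(E)] <- NA
  f <- apply(E, 2, summary, na.rm = TRUE)
  f <- f / exp(mean(log(f)))
  tibble(sample = colnames(ip), size_factor = unname(f))
}

#' Adjust normalized IP counts for pre-IP gene expression
#'
#' A gene-wise size factor is computed per sample by centering normalized
#' gene-level counts to mean 1 across samples; each bin's normalized IP
#' count is divided by the factor of its gene. The result reflects
#' methylation level with expression, depth and IP efficiency accounted
#' for. Samples where a gene has zero counts get a floored factor
#' (`eps_frac` x the gene's mean factor) to avoid division blow-up.
#'
#' @param norm_ip normalized IP matrix bins x samples
#' @param gene_id gene assignment of each bin (length nrow(norm_ip))
#' @param norm_genes normalized gene count matrix with rownames gene_id
#' @param eps_frac floor for the gene factor, as a fraction of the row mean
#' @return list with `adjusted_ip` (bins x samples) and `gene_factors`
#'   (genes x samples, row mean 1)
#' @export
expression_adjust <- function(norm_ip, gene_id, norm_genes, eps_frac = 0.1) {
  gf <- norm_genes / rowMeans(norm_genes)
  gf[is.nan(gf)] <- 1  # all-zero gene: neutral factor
  zero <- gf <= 0
  if (any(zero)) {
    warning(sum(zero), " gene/sample cells with zero expression; ",
            "gene factor floored at ", eps_frac, " x row mean")
    floor_m <- matrix(eps_frac * rowMeans(gf), nrow(gf), ncol(gf))
    gf[zero] <- floor_m[zero]
  }
  i <- match(gene_id, rownames(norm_genes))
  if (anyNA(i)) stop("bins reference genes absent from norm_genes")
  list(adjusted_ip = norm_ip / gf[i, , drop = FALSE], gene_factors = gf)
}

#' Run the full normalization stage
#'
#' Chains [input_size_factors()], [ip_size_factors()] and
#' [expression_adjust()]; also records the raw fold-enrichment matrix
#' E = IP / normalized geneSum used by the depletion filter.
#'
#' @inheritParams ip_size_factors
#' @param eps_frac see [expression_adjust()]
#' @return object of class `merip_norm`: list with tibbles `size_factors`
#'   (sample, input_sf, ip_sf), `adjusted_ip`, `enrichment` (both with bin
#'   key columns), matrices `norm_gene_counts`, `gene_factors`, and the bin
#'   `keys`
#' @export
normalize_merip <- function(counts, top_frac = 0.01, summary = "mean",
                            eps_frac = 0.1) {
  gs <- gene_sum(counts)
  isf <- input_size_factors(gs)
  ng <- attr(isf, "norm_gene_counts")
  rownames(ng) <- gs$gene_id
  sf_ip <- ip_size_factors(counts, ng, top_frac = top_frac, summary = summary)
  ip <- count_matrix(counts, "ip")
  norm_ip <- sweep(ip, 2, sf_ip$size_factor, "/")
  adj <- expression_adjust(norm_ip, counts$gene_id, ng, eps_frac = eps_frac)
  E <- ip / ng[match(counts$gene_id, rownames(ng)), , drop = FALSE]
  keys <- bin_keys(counts)
  out <- list(
    size_factors = tibble(sample = isf$sample,
                          input_sf = isf$size_factor,
                          ip_sf = sf_ip$size_factor),
    adjusted_ip = bind_cols(keys, as_tibble(adj$adjusted_ip)),
    enrichment = bind_cols(keys, as_tibble(E)),
    norm_gene_counts = ng,
    gene_factors = adj$gene_factors,
    keys = keys,
    raw_ip_mean = rowMeans(ip)
  )
  class(out) <- "merip_norm"
  out
}

#' @export
print.merip_norm <- function(x, ...) {
  cat("MeRIP normalization:", nrow(x$keys), "bins,",
      nrow(x$size_factors), "samples\n")
  print(x$size_factors)
  invisible(x)
}

#' Principal components of m6A enrichment
#'
#' PCA of log1p-transformed adjusted IP counts across samples, a diagnostic
#' for batch effects and confounding. When `covariates` is supplied each
#' bin's log enrichment is first residualized on the covariates by least
#' squares, mirroring "regressing out" a known batch.
#'
#' @param adjusted_ip bins x samples matrix, or the `adjusted_ip` tibble of a
#'   [normalize_merip()] result
#' @param covariates optional data frame of per-sample covariates to regress
#'   out before the PCA
#' @return tibble with `sample`, `PC1`, `PC2` and attribute
#'   `"var_explained"`
#' @export
enrichment_pca <- function(adjusted_ip, covariates = NULL) {
  m <- if (is.matrix(adjusted_ip)) adjusted_ip else count_matrix_any(adjusted_ip)
  if (ncol(m) < 3) stop("need >= 3 samples for a PCA diagnostic")
  lm1 <- log1p(m)
  if (!is.null(covariates)) {
    X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    lm1 <- t(stats::lm.fit(X, t(lm1))$residuals)
  }
  v <- apply(lm1, 1, stats::sd)
  if (all(v == 0)) {
    warning("constant enrichment matrix: zero variance, coordinates all 0")
    return(tibble(sample = colnames(m), PC1 = 0, PC2 = 0))
  }
  pc <- prcomp(t(lm1[v > 0, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  out <- tibble(sample = colnames(m),
                PC1 = pc$x[, 1],
                PC2 = if (k >= 2) pc$x[, 2] else 0)
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:k]
  out
}

# numeric sample columns of a keyed tibble
count_matrix_any <- function(x) {
  as.matrix(x[setdiff(names(x), KEY_COLS)])
}
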