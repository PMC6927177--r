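gene_tbl <- function(m) {
  colnames(m) <- paste0("input_", colnames(m))
  dplyr::bind_cols(tibble::tibble(gene_id = sprintf("g%03d", seq_len(nrow(m)))),
                   tibble::as_tibble(m))
}

test_that("median-of-ratios size factors match hand computation and DESeq2", {
  m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- input_size_factors(gene_tbl(m))
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)))

  # identical columns -> unit factors; zero gene is ignored
  m2 <- cbind(A = c(5, 9, 13), B = c(5, 9, 13))
  expect_equal(input_size_factors(gene_tbl(m2))$size_factor, c(1, 1))
  m3 <- rbind(m, c(0, 0))
  expect_equal(input_size_factors(gene_tbl(m3))$size_factor,
               sf$size_factor)

  # independent oracle on a random matrix
  set.seed(21)
  m4 <- matrix(rnbinom(200 * 5, mu = 80, size = 3), 200, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  ours <- input_size_factors(gene_tbl(m4))$size_factor
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m4)
  # DESeq2 takes the median of log ratios; with an even gene count the
  # interpolated middle differs from the raw-ratio median in the 6th digit
  expect_equal(ours, unname(oracle), tolerance = 1e-4)
})

test_that("median-of-ratios is exactly scale equivariant in factor ratios", {
  # the geometric-mean reference rescales with the column, so the gauge-free
  # statement is about ratios: scaling sample j by k multiplies every ratio
  # factor[j]/factor[j'] by exactly k
  set.seed(22)
  m <- matrix(rnbinom(100 * 4, mu = 50, size = 5) + 1, 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  base <- input_size_factors(gene_tbl(m))$size_factor
  m2 <- m; m2[, 3] <- m2[, 3] * 7
  scaled <- input_size_factors(gene_tbl(m2))$size_factor
  expect_equal(scaled[3] / scaled[-3], 7 * base[3] / base[-3],
               tolerance = 1e-12)
  expect_equal(scaled[1] / scaled[2], base[1] / base[2], tolerance = 1e-12)
})

test_that("errors: too few samples, no common gene, bad top fraction", {
  expect_error(input_size_factors(gene_tbl(cbind(A = c(1, 2)))), "2 samples")
  m <- cbind(A = c(5, 0), B = c(0, 5))
  expect_error(input_size_factors(gene_tbl(m)), "positive")
})

test_that("IP size factors recover a planted efficiency difference", {
  set.seed(30)
  n_bins <- 1000; n_genes <- 100
  gene_id <- rep(sprintf("g%03d", 1:n_genes), each = 10)
  keys <- tibble::tibble(gene_id = gene_id, bin_index = rep(0:9, n_genes),
                         tx_start = rep(0:9, n_genes) * 50L,
                         tx_end = rep(1:10, n_genes) * 50L)
  input <- matrix(rpois(n_bins * 2, 30), n_bins, 2,
                  dimnames = list(NULL, c("a", "b")))
  base_ip <- rpois(n_bins, ifelse(seq_len(n_bins) %% 25 == 0, 400, 20))
  ip <- cbind(a = rpois(n_bins, base_ip + 0.1),
              b = rpois(n_bins, 2 * (base_ip + 0.1)))  # b has 2x efficiency
  counts <- meripdm:::new_counts_tbl(keys, input = input, ip = ip)
  gs <- gene_sum(counts)
  isf <- input_size_factors(gs)
  ng <- attr(isf, "norm_gene_counts"); rownames(ng) <- gs$gene_id
  sf <- ip_size_factors(counts, ng, top_frac = 0.05)
  expect_equal(sf$size_factor[2] / sf$size_factor[1], 2, tolerance = 0.05)
  expect_equal(exp(mean(log(sf$size_factor))), 1, tolerance = 1e-12)

  expect_error(ip_size_factors(counts, ng, top_frac = 0.5), "top_frac")
  expect_error(ip_size_factors(counts[1:8, ], ng, top_frac = 0.01),
               "top bins")
})

test_that("expression adjustment centres gene factors and cancels expression", {
  ng <- rbind(g1 = c(4, 4, 4, 4), g2 = c(1, 1, 3, 3))
  norm_ip <- matrix(1, 2, 4)
  adj <- expression_adjust(norm_ip, c("g1", "g2"), ng)
  expect_equal(unname(adj$gene_factors["g2", ]), c(0.5, 0.5, 1.5, 1.5))
  expect_equal(unname(adj$gene_factors["g1", ]), rep(1, 4))
  expect_equal(rowMeans(adj$gene_factors), c(g1 = 1, g2 = 1), tolerance = 1e-9)
  # equally expressed gene: adjusted == normalized
  expect_equal(adj$adjusted_ip[1, ], norm_ip[1, ])

  # IP proportional to expression -> adjusted constant across samples
  expr <- c(2, 4, 6, 8)
  ng2 <- rbind(gX = expr)
  ip2 <- matrix(5 * expr, 1, 4)
  adj2 <- expression_adjust(ip2, "gX", ng2)
  expect_equal(drop(adj2$adjusted_ip), rep(5 * mean(expr), 4))

  # zero-count sample floored with warning, stays finite
  ng3 <- rbind(gZ = c(0, 2, 2, 2))
  expect_warning(adj3 <- expression_adjust(matrix(1, 1, 4), "gZ", ng3),
                 "floored")
  expect_true(all(is.finite(adj3$adjusted_ip)))
})

test_that("adjusted IP is invariant (up to gauge) to joint library rescaling", {
  set.seed(77)
  n_bins <- 1200
  keys <- tibble::tibble(gene_id = rep(sprintf("g%03d", 1:120), each = 10),
                         bin_index = rep(0:9, 120),
                         tx_start = rep(0:9, 120) * 50L,
                         tx_end = rep(1:10, 120) * 50L)
  input <- matrix(rpois(n_bins * 4, 25) + 1L, n_bins, 4,
                  dimnames = list(NULL, paste0("S", 1:4)))
  # plant exactly as many unambiguous top bins as the top set holds, so the
  # selected set is identical before and after rescaling
  ip_mu <- rep(15, n_bins); ip_mu[seq(1, n_bins, by = 50)] <- 600
  ip <- sapply(1:4, function(j) rpois(n_bins, ip_mu))
  colnames(ip) <- paste0("S", 1:4)
  counts <- meripdm:::new_counts_tbl(keys, input = input, ip = ip)

  norm1 <- normalize_merip(counts, top_frac = 0.02)
  counts2 <- counts
  counts2$input_S3 <- counts2$input_S3 * 5L
  counts2$ip_S3 <- counts2$ip_S3 * 5L
  norm2 <- normalize_merip(counts2, top_frac = 0.02)
  a1 <- meripdm:::count_matrix_any(norm1$adjusted_ip)
  a2 <- meripdm:::count_matrix_any(norm2$adjusted_ip)
  ok <- a1 > 0
  ratio <- a2[ok] / a1[ok]
  # every entry shifts by one common gauge constant only
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-10)
})

test_that("normalization is deterministic", {
  d <- quick_sim(n_bins = 1500, seed = 5)
  n1 <- normalize_merip(d$counts)
  n2 <- normalize_merip(d$counts)
  expect_identical(n1$size_factors, n2$size_factors)
  expect_identical(n1$adjusted_ip, n2$adjusted_ip)
})

test_that("enrichment PCA separates planted clusters and removes batch", {
  set.seed(41)
  n_bins <- 500
  base <- rlnorm(n_bins, log(20), 0.5)
  grp <- rep(0:1, each = 3)
  m <- sapply(grp, function(g) {
    x <- base
    x[1:100] <- x[1:100] * ifelse(g == 1, 4, 1)  # 20% of bins differ
    rpois(n_bins, x)
  })
  colnames(m) <- paste0("s", 1:6)
  pc <- enrichment_pca(m)
  expect_gt(abs(mean(pc$PC1[grp == 1]) - mean(pc$PC1[grp == 0])),
            2 * max(stats::sd(pc$PC1[grp == 0]), stats::sd(pc$PC1[grp == 1])))

  # batch orthogonal to group; residualizing removes batch separation
  batch <- rep(c(0, 1), 3)
  m2 <- sweep(m, 2, ifelse(batch == 1, 3, 1), "*")
  pc_raw <- enrichment_pca(m2)
  pc_res <- enrichment_pca(m2, covariates = data.frame(batch = batch))
  sep <- function(pc, lab) {
    abs(mean(pc$PC1[lab == 1]) - mean(pc$PC1[lab == 0])) /
      (stats::sd(pc$PC1) + 1e-9)
  }
  expect_gt(sep(pc_raw, batch), sep(pc_res, batch))
  expect_gt(sep(pc_res, grp), sep(pc_res, batch))

  expect_warning(pc0 <- enrichment_pca(matrix(3, 10, 4,
    dimnames = list(NULL, paste0("s", 1:4)))), "zero variance")
  expect_true(all(pc0$PC1 == 0 & pc0$PC2 == 0))
})
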