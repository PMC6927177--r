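
#' Generator settings for simulated MeRIP-seq datasets
#'
#' Defaults describe a typical deeply sequenced MeRIP-seq experiment: per-bin
#' mean enrichment counts log-normal with median 30 reads, random-effect
#' scale psi log-uniform on [0.5, 20], gene-level INPUT depth log-normal
#' with median 272 reads, 10 bins per gene, INPUT counts negative binomial
#' with shape 10 (biological CV ~ 0.3), and IP libraries rescaled to a mean
#' IP/INPUT ratio of 1. The confounded binary covariate, when requested, is
#' assigned 3:1 in one group and 1:3 in the other.
#'
#' @param mu_median median of the per-bin mean count distribution
#' @param mu_sdlog log-sd of the per-bin mean count distribution
#' @param psi_range range of the log-uniform random-effect scale
#' @param gene_depth_median,gene_depth_sdlog log-normal gene INPUT depth
#' @param bins_per_gene bins per simulated gene
#' @param input_shape NB shape of INPUT counts across replicates
#' @param ip_input_ratio target mean IP / mean INPUT bin count
#' @param covariate_balance fraction of group-1... of each group assigned
#'   covariate level 1 in group 0 (and `1 -` that in group 1)
#' @return list of class `merip_sim_config`
#' @export
sim_config <- function(mu_median = 30, mu_sdlog = 1, psi_range = c(0.5, 20),
                       gene_depth_median = 272, gene_depth_sdlog = 1,
                       bins_per_gene = 10, input_shape = 10,
                       ip_input_ratio = 1, covariate_balance = 0.75) {
  stopifnot(mu_median > 0, mu_sdlog >= 0, length(psi_range) == 2,
            all(psi_range > 0), bins_per_gene >= 1, input_shape > 0,
            ip_input_ratio > 0, covariate_balance > 0, covariate_balance < 1)
  structure(as.list(environment()), class = "merip_sim_config")
}

sim_frame <- function(n_bins, n_samples, truth_frac, gen) {
  if (n_samples %% 2 != 0) stop("n_samples must be even (two equal groups)")
  if (truth_frac <= 0 || truth_frac >= 1) stop("truth_frac must be in (0,1)")
  n_genes <- ceiling(n_bins / gen$bins_per_gene)
  gene_id <- sprintf("g%05d", rep(seq_len(n_genes), each = gen$bins_per_gene))[1:n_bins]
  bin_index <- unlist(lapply(rle(gene_id)$lengths, seq_len)) - 1L
  keys <- tibble(gene_id = gene_id, bin_index = bin_index,
                 tx_start = bin_index * 50L, tx_end = bin_index * 50L + 50L)
  truth <- rep(FALSE, n_bins)
  truth[sample.int(n_bins, floor(truth_frac * n_bins))] <- TRUE
  list(keys = keys, truth = truth, n_genes = n_genes)
}

sim_design <- function(n_samples, covariate_effect, gen) {
  grp <- rep(0:1, each = n_samples / 2)
  design <- tibble(sample = paste0("S", seq_len(n_samples)), group = grp)
  if (!is.null(covariate_effect)) {
    half <- n_samples / 2
    k1 <- round(gen$covariate_balance * half)
    cov <- c(rep(1L, k1), rep(0L, half - k1),        # group 0: mostly level 1
             rep(1L, half - k1), rep(0L, k1))        # group 1: mostly level 0
    design$batch <- cov
  }
  design
}

#' Simulate enrichment counts from the Poisson-log-gamma model
#'
#' Per bin, an intercept mu_i and random-effect scale psi_i are drawn from
#' the generator distributions; per sample, w ~ Gamma(psi_i, psi_i) and
#' Y ~ Poisson(exp(mu_i + group x beta0 [+ batch x covariate_effect]) w).
#' beta0 applies only at the `truth_frac` bins pre-defined as true DM sites
#' (label assignment is deterministic in count: exactly
#' `floor(truth_frac * n_bins)` true bins). INPUT bin counts are drawn
#' NB around gene depth / bins-per-gene, and raw IP counts are the
#' simulated Y rescaled to the target mean IP/INPUT ratio.
#'
#' @param n_bins number of bins (default 26324)
#' @param n_samples even number of samples, split n/2 vs n/2 (default 8)
#' @param truth_frac fraction of true DM bins (default 0.2)
#' @param beta0 DM effect size on the log scale (default 0.75)
#' @param covariate_effect effect of a confounded binary covariate on the
#'   log enrichment, or `NULL` (default) for the simple case
#' @param gen generator settings from [sim_config()]
#' @param seed integer seed; identical (config, seed) give bit-identical
#'   datasets
#' @return object of class `merip_sim`: list with `counts` (merip_counts
#'   tibble of raw INPUT/IP bin counts), `enrichment` (bin keys + per-sample
#'   processed IP counts Y, the quantity the DM model tests), `design`,
#'   `truth` (keys + `is_dm` + `beta0_true`), `params` (mu, psi per bin),
#'   `gene_counts`, `config`, `seed`
#' @export
simulate_pois_gamma <- function(n_bins = 26324, n_samples = 8,
                                truth_frac = 0.2, beta0 = 0.75,
                                covariate_effect = NULL,
                                gen = sim_config(), seed = 1) {
  set.seed(seed)
  fr <- sim_frame(n_bins, n_samples, truth_frac, gen)
  design <- sim_design(n_samples, covariate_effect, gen)
  mu <- log(rlnorm(n_bins, log(gen$mu_median), gen$mu_sdlog))
  psi <- exp(runif(n_bins, log(gen$psi_range[1]), log(gen$psi_range[2])))
  b0 <- ifelse(fr$truth, beta0, 0)
  eta <- outer(mu, rep(1, n_samples)) + outer(b0, design$group)
  if (!is.null(covariate_effect))
    eta <- eta + outer(rep(covariate_effect, n_bins), design$batch)
  w <- matrix(rgamma(n_bins * n_samples, shape = psi, rate = psi),
              n_bins, n_samples)
  Y <- matrix(rpois(n_bins * n_samples, exp(eta) * w), n_bins, n_samples)
  colnames(Y) <- design$sample

  # INPUT: gene depth shared across bins of a gene, NB across replicates
  depth <- rlnorm(fr$n_genes, log(gen$gene_depth_median), gen$gene_depth_sdlog)
  bin_mu <- depth[as.integer(factor(fr$keys$gene_id))] / gen$bins_per_gene
  input <- matrix(rnbinom(n_bins * n_samples, mu = bin_mu,
                          size = gen$input_shape), n_bins, n_samples)
  colnames(input) <- design$sample

  scale <- gen$ip_input_ratio * mean(input) / mean(Y)
  ip <- round(Y * scale)

  out <- list(
    counts = new_counts_tbl(fr$keys, input = input, ip = ip),
    enrichment = bind_cols(fr$keys, as_tibble(Y)),
    design = design,
    truth = bind_cols(fr$keys, tibble(is_dm = fr$truth, beta0_true = b0)),
    params = bind_cols(fr$keys, tibble(mu = mu, psi = psi)),
    gene_counts = rowsum(input, fr$keys$gene_id),
    config = gen, seed = seed, model = "pois_gamma"
  )
  class(out) <- "merip_sim"
  out
}

#' Simulate paired INPUT/IP counts from a quad-negative-binomial model
#'
#' INPUT and IP counts are drawn from independent negative binomials per
#' bin; the IP dispersion (1/shape) is `dispersion_ratio` times the INPUT
#' dispersion, reflecting the extra noise of the immunoprecipitation step.
#' The DM effect multiplies the IP mean of group 1 at true bins by
#' exp(beta0); the covariate, when present, multiplies the IP mean of its
#' samples by exp(covariate_effect).
#'
#' @inheritParams simulate_pois_gamma
#' @param dispersion_ratio IP dispersion / INPUT dispersion (>= 1,
#'   default 10)
#' @return a `merip_sim` object (see [simulate_pois_gamma()]); here
#'   `enrichment` carries the raw IP counts since no random-effect layer
#'   exists
#' @export
simulate_qnb <- function(n_bins = 26324, n_samples = 8, truth_frac = 0.2,
                         beta0 = 0.75, covariate_effect = NULL,
                         dispersion_ratio = 10, gen = sim_config(),
                         seed = 1) {
  if (dispersion_ratio < 1) stop("dispersion_ratio must be >= 1")
  set.seed(seed)
  fr <- sim_frame(n_bins, n_samples, truth_frac, gen)
  design <- sim_design(n_samples, covariate_effect, gen)
  m <- rlnorm(n_bins, log(gen$mu_median), gen$mu_sdlog)
  size_in <- exp(runif(n_bins, log(gen$psi_range[1]), log(gen$psi_range[2])))
  size_ip <- size_in / dispersion_ratio
  b0 <- ifelse(fr$truth, beta0, 0)
  lmean_ip <- outer(log(m), rep(1, n_samples)) + outer(b0, design$group)
  if (!is.null(covariate_effect))
    lmean_ip <- lmean_ip + outer(rep(covariate_effect, n_bins), design$batch)
  ip <- matrix(rnbinom(n_bins * n_samples, mu = exp(lmean_ip),
                       size = size_ip), n_bins, n_samples)
  input <- matrix(rnbinom(n_bins * n_samples, mu = m / gen$ip_input_ratio,
                          size = size_in), n_bins, n_samples)
  colnames(ip) <- colnames(input) <- design$sample
  out <- list(
    counts = new_counts_tbl(fr$keys, input = input, ip = ip),
    enrichment = bind_cols(fr$keys, as_tibble(ip)),
    design = design,
    truth = bind_cols(fr$keys, tibble(is_dm = fr$truth, beta0_true = b0)),
    params = bind_cols(fr$keys, tibble(mu = log(m), psi = size_in)),
    gene_counts = rowsum(input, fr$keys$gene_id),
    config = c(gen, dispersion_ratio = dispersion_ratio),
    seed = seed, model = "qnb"
  )
  class(out) <- "merip_sim"
  out
}

#' @export
print.merip_sim <- function(x, ...) {
  cat("Simulated MeRIP-seq dataset (", x$model, " model): ",
      nrow(x$truth), " bins x ", nrow(x$design), " samples, ",
      sum(x$truth$is_dm), " true DM bins, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Sensitivity and empirical FDR of a set of DM calls
#'
#' Predicted DM bins are those with `padj < cutoff`. Sensitivity is the
#' fraction of true DM bins among the predictions' overlap with truth;
#' empirical FDR is the fraction of predictions that are not true bins (0
#' when nothing is predicted).
#'
#' @param results tibble with bin keys and a `padj` column ([dm_test()] or
#'   [fisher_comparator()] output)
#' @param truth the `truth` tibble of a `merip_sim` dataset
#' @param cutoff BH cutoff defining predictions (default 0.1)
#' @return one-row tibble: `cutoff`, `n_pred`, `n_true`, `sensitivity`,
#'   `empirical_fdr`
#' @export
evaluate_calls <- function(results, truth, cutoff = 0.1) {
  key <- c("gene_id", "bin_index")
  orphan <- dplyr::anti_join(results[key], truth[key], by = key)
  if (nrow(orphan)) stop("result bin keys do not match truth")
  j <- left_join(truth[c(key, "is_dm")], results[c(key, "padj")], by = key)
  if (nrow(j) != nrow(truth)) stop("result bin keys do not match truth")
  pred <- !is.na(j$padj) & j$padj < cutoff
  n_true <- sum(j$is_dm)
  tibble(cutoff = cutoff, n_pred = sum(pred), n_true = n_true,
         sensitivity = sum(pred & j$is_dm) / n_true,
         empirical_fdr = if (any(pred)) sum(pred & !j$is_dm) / sum(pred) else 0)
}

#' Pooled-count Fisher's exact test comparator
#'
#' The classical MeRIP-seq comparator: per bin, read counts are summed over
#' the replicates of each group and the 2x2 table
#' (IP group1, INPUT group1; IP group2, INPUT group2) is tested two-sided
#' with Fisher's exact test. Pooling ignores within-group biological
#' variability, which is exactly why this test over-detects; it is included
#' as a benchmark baseline. Covariates are ignored by construction.
#'
#' @param counts a `merip_counts` tibble with raw INPUT and IP columns
#' @param design design tibble with `sample` and two-level `group`
#' @return tibble of bin keys plus `p.value` and BH `padj`
#' @export
fisher_comparator <- function(counts, design) {
  input <- count_matrix(counts, "input")
  ip <- count_matrix(counts, "ip")
  M <- design_matrix(design, colnames(ip))
  g1 <- M[, "group"] == 0
  t1 <- rowSums(ip[, g1, drop = FALSE]);  t2 <- rowSums(ip[, !g1, drop = FALSE])
  c1 <- rowSums(input[, g1, drop = FALSE]); c2 <- rowSums(input[, !g1, drop = FALSE])
  p <- vapply(seq_along(t1), function(i) {
    tab <- matrix(c(t1[i], c1[i], t2[i], c2[i]), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    fisher.test(tab)$p.value
  }, 0)
  bind_cols(bin_keys(counts), tibble(p.value = p,
                                     padj = p.adjust(p, method = "BH")))
}

#' Power and FDR across sample sizes
#'
#' Simulates `copies` datasets per sample size, runs the random-effect DM
#' test on the simulated enrichment counts, and records sensitivity and
#' empirical FDR at the given BH cutoff. Larger cohorts buy power and
#' calibration; fewer than ~ 3 replicates per group is unreliable.
#'
#' @param beta0 DM effect size (default 0.75)
#' @param n_grid even sample sizes to sweep (default 2, 4, 6, 8)
#' @param copies simulated datasets per sample size (default 3; the
#'   benchmark in routine use ran 10)
#' @param n_bins bins per dataset
#' @param cutoff BH cutoff (default 0.1)
#' @param gen generator settings
#' @param seed base seed; copy c of size n uses seed + 89 * c + n
#' @return `merip_benchmark` tibble: `n`, `copy`, `sensitivity`,
#'   `empirical_fdr`, `cutoff`, `beta0`
#' @export
sample_size_sweep <- function(beta0 = 0.75, n_grid = c(2, 4, 6, 8),
                              copies = 3, n_bins = 26324, cutoff = 0.1,
                              gen = sim_config(), seed = 1) {
  stopifnot(all(n_grid %% 2 == 0), copies >= 1)
  out <- purrr::map_dfr(n_grid, function(n) {
    purrr::map_dfr(seq_len(copies), function(cp) {
      d <- simulate_pois_gamma(n_bins = n_bins, n_samples = n,
                               truth_frac = 0.2, beta0 = beta0, gen = gen,
                               seed = seed + 89L * cp + n)
      dm <- dm_test(d$enrichment, d$design)
      ev <- evaluate_calls(dm, d$truth, cutoff = cutoff)
      tibble(n = n, copy = cp, sensitivity = ev$sensitivity,
             empirical_fdr = ev$empirical_fdr, cutoff = cutoff, beta0 = beta0)
    })
  })
  class(out) <- c("merip_benchmark", class(out))
  out
}
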