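
#' Filter bins before differential testing
#'
#' Two pre-specified, group-blind filters: (a) bins whose mean raw IP count
#' across samples falls below `min_ip` (too noisy to test, and likely
#' unmethylated anyway), and (b) IP-depleted bins whose mean fold enrichment
#' E = IP / normalized geneSum across samples falls below `min_enrichment`
#' (counts there mostly reflect non-specific antibody binding).
#'
#' @param norm a `merip_norm` object from [normalize_merip()]
#' @param min_ip minimum mean raw IP count (default 15)
#' @param min_enrichment minimum mean fold enrichment (default 1)
#' @return tibble of bin keys plus logical `keep`
#' @export
filter_bins <- function(norm, min_ip = 15, min_enrichment = 1) {
  E <- count_matrix_any(norm$enrichment)
  keep <- norm$raw_ip_mean >= min_ip & rowMeans(E, na.rm = TRUE) >= min_enrichment
  if (!any(keep))
    stop("no bins pass the filters; consider lowering min_ip (", min_ip, ")")
  bind_cols(norm$keys, tibble(keep = keep))
}

#' Marginal log-likelihood of the Poisson-log-gamma model
#'
#' For counts Y with log-mean eta = mu + X beta and a multiplicative
#' Gamma(psi, psi) random effect, the random effect integrates out to
#' `sum_i Y_i eta_i + psi log psi + log Gamma(Y_i + psi) - log Y_i! -
#' log Gamma(psi) - (Y_i + psi) log(exp(eta_i) + psi)`,
#' i.e. the negative binomial likelihood with shape psi and mean exp(eta).
#'
#' @param y non-negative integer counts
#' @param X design matrix (n x k) of group indicator and covariates, without
#'   intercept; `NULL` for an intercept-only model
#' @param mu intercept
#' @param beta coefficient vector matching `ncol(X)`
#' @param psi positive random-effect scale
#' @return scalar log-likelihood
#' @export
pg_loglik <- function(y, X, mu, beta, psi) {
  check_pg_args(y, psi)
  eta <- drop(mu + xbeta(X, beta, length(y)))
  a <- pmax(eta, log(psi))
  lse <- a + log(exp(eta - a) + exp(log(psi) - a))
  sum(y * eta + psi * log(psi) + lgamma(y + psi) - lgamma(y + 1) -
        lgamma(psi) - (y + psi) * lse)
}

#' Analytic gradient of the marginal log-likelihood
#'
#' First derivatives over (mu, beta, psi); the psi component carries the
#' digamma terms of the Gamma mixing density.
#'
#' @inheritParams pg_loglik
#' @return named vector `(mu, beta1..k, psi)`
#' @export
pg_loglik_grad <- function(y, X, mu, beta, psi) {
  check_pg_args(y, psi)
  eta <- drop(mu + xbeta(X, beta, length(y)))
  a <- pmax(eta, log(psi))
  lse <- a + log(exp(eta - a) + exp(log(psi) - a))
  frac <- exp(eta - lse)
  resid <- y - (y + psi) * frac
  g_mu <- sum(resid)
  g_beta <- if (is.null(X)) numeric(0) else drop(crossprod(as.matrix(X), resid))
  g_psi <- sum(log(psi) + 1 - (y + psi) * exp(-lse) - lse +
                 digamma(y + psi) - digamma(psi))
  c(mu = g_mu,
    setNames(g_beta, if (length(g_beta)) paste0("beta", seq_along(g_beta))),
    psi = g_psi)
}

check_pg_args <- function(y, psi) {
  if (psi <= 0) stop("psi must be > 0")
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
}

xbeta <- function(X, beta, n) {
  if (is.null(X)) return(rep(0, n))
  as.matrix(X) %*% beta
}

#' Fit the Poisson-log-gamma model to one bin
#'
#' Maximizes the marginal log-likelihood by gradient ascent with Armijo
#' backtracking line search; psi is optimized on the log scale so positivity
#' needs no projection. Initial values: mu = log(mean(y) + 0.5), beta = 0,
#' psi by method of moments clipped to [0.1, 1e4]. The standard error of the
#' group coefficient comes from the observed Fisher information (central
#' finite differences of the analytic gradient at the MLE); when the psi
#' direction is flat the regression block is inverted instead.
#'
#' @param y non-negative integer counts (>= 4 observations)
#' @param X design matrix without intercept; first column must be the group
#'   indicator
#' @param tol convergence tolerance on the log-likelihood increase
#' @param max_iter maximum gradient-ascent iterations
#' @return object of class `merip_fit` with elements `coef` (named:
#'   intercept, group, covariates), `psi`, `se_beta0`, `loglik`, `n_iter`,
#'   `converged`, `info_code` (0 full inverse, 1 regression block, 2
#'   singular)
#' @export
fit_bin <- function(y, X, tol = 1e-8, max_iter = 1000) {
  X <- as.matrix(X)
  if (length(y) < 4) stop("need >= 4 observations per bin")
  if (length(unique(X[, 1])) < 2) stop("both groups must be represented")
  M <- cbind(1, X)
  r <- .fit_bin_cpp(as.numeric(y), M, tol, as.integer(max_iter))
  p <- ncol(M)
  nm <- c("intercept", "group",
          if (p > 2) paste0("covar", seq_len(p - 2)))
  out <- list(coef = setNames(r[1:p], nm), psi = r[p + 1],
              se_beta0 = r[p + 2], loglik = r[p + 3],
              n_iter = as.integer(r[p + 4]), converged = r[p + 5] == 1,
              info_code = as.integer(r[p + 6]),
              y = y, X = X)
  class(out) <- "merip_fit"
  out
}

#' @export
print.merip_fit <- function(x, ...) {
  cat("Poisson-log-gamma fit: logLik", format(x$loglik, digits = 6),
      if (x$converged) "(converged," else "(NOT converged,",
      x$n_iter, "iterations)\n")
  print(round(c(x$coef, psi = x$psi), 4))
  invisible(x)
}

#' Wald test of the group effect
#'
#' Tests beta0 = 0 with z = beta0 / se(beta0), se from observed Fisher
#' information; two-sided normal p-value. A singular information matrix
#' yields p = 1 with a diagnostic flag.
#'
#' @param fit a `merip_fit` from [fit_bin()]
#' @return one-row tibble: `estimate`, `se`, `statistic`, `p.value`,
#'   `singular`
#' @export
wald_test <- function(fit) {
  b0 <- unname(fit$coef["group"])
  if (fit$info_code == 2 || !is.finite(fit$se_beta0)) {
    return(tibble(estimate = b0, se = NA_real_, statistic = NA_real_,
                  p.value = 1, singular = TRUE))
  }
  z <- b0 / fit$se_beta0
  tibble(estimate = b0, se = fit$se_beta0, statistic = z,
         p.value = 2 * pnorm(-abs(z)), singular = FALSE)
}

#' Differential methylation test over all retained bins
#'
#' Rounds the adjusted IP counts half-to-even to integers (the model is a
#' count model), fits every retained bin, and applies Benjamini-Hochberg
#' adjustment across the tested bins. Swapping the group labels flips the
#' sign of the estimate and leaves p-values unchanged.
#'
#' @param adjusted_ip a `merip_norm` object, or a tibble of bin keys plus
#'   one numeric column per sample (e.g. the `enrichment` counts of a
#'   simulated dataset)
#' @param design tibble with columns `sample`, `group` (two levels, coded
#'   0/1 or factor) and optional covariate columns; column order of the
#'   count matrix must match `design$sample`
#' @param mask optional filter tibble from [filter_bins()] (or logical
#'   vector); defaults to testing every bin
#' @param keep_nonconverged include non-converged fits in the BH adjustment
#'   (default FALSE: they are reported with `padj = NA` and flagged)
#' @param tol,max_iter optimizer controls, see [fit_bin()]
#' @return `merip_dm` tibble, one row per tested bin, sorted by gene and
#'   position: bin keys, `mu`, `lfc` (group log fold change), `se`,
#'   `statistic`, `p.value`, `padj`, `psi`, `n_iter`, `converged`
#' @export
dm_test <- function(adjusted_ip, design, mask = NULL,
                    keep_nonconverged = FALSE, tol = 1e-8, max_iter = 1000) {
  if (inherits(adjusted_ip, "merip_norm")) adjusted_ip <- adjusted_ip$adjusted_ip
  keys <- bin_keys(adjusted_ip)
  m <- count_matrix_any(adjusted_ip)
  if (!is.null(mask)) {
    keep <- if (is.logical(mask)) mask else mask$keep
    keys <- keys[keep, , drop = FALSE]
    m <- m[keep, , drop = FALSE]
  }
  M <- design_matrix(design, colnames(m))
  Y <- round(m)  # half-to-even; Poisson likelihood needs integers
  res <- .fit_bins_cpp(Y, M, tol, as.integer(max_iter))
  p <- ncol(M)
  se <- res[, p + 2]
  z <- res[, 2] / se
  pval <- 2 * pnorm(-abs(z))
  singular <- res[, p + 6] == 2 | !is.finite(pval)
  pval[singular] <- 1
  converged <- res[, p + 5] == 1
  use <- if (keep_nonconverged) rep(TRUE, nrow(res)) else converged
  padj <- rep(NA_real_, nrow(res))
  padj[use] <- p.adjust(pval[use], method = "BH")
  out <- bind_cols(keys, tibble(
    mu = res[, 1], lfc = res[, 2], se = se, statistic = z,
    p.value = pval, padj = padj, psi = res[, p + 1],
    n_iter = as.integer(res[, p + 4]), converged = converged,
    singular = singular
  ))
  if (all(c("gene_id", "tx_start") %in% names(out)))
    out <- arrange(out, .data$gene_id, .data$tx_start)
  class(out) <- c("merip_dm", class(out))
  attr(out, "design") <- design
  out
}

# model matrix (intercept | group | covariates) aligned to sample order
design_matrix <- function(design, samples) {
  stopifnot(all(c("sample", "group") %in% names(design)))
  if (!is.null(samples)) {
    i <- match(samples, design$sample)
    if (anyNA(i)) stop("design is missing samples: ",
                       paste(samples[is.na(i)], collapse = ", "))
    design <- design[i, ]
  }
  grp <- design$group
  if (is.factor(grp) || is.character(grp)) grp <- as.integer(factor(grp)) - 1L
  if (length(unique(grp)) != 2) stop("group must have exactly two levels")
  if (min(table(grp)) < 2) warning("fewer than 2 samples in a group")
  covars <- design[setdiff(names(design), c("sample", "group"))]
  M <- cbind(intercept = 1, group = grp)
  if (ncol(covars)) {
    cm <- stats::model.matrix(~ ., data = as.data.frame(covars))[, -1, drop = FALSE]
    M <- cbind(M, cm)
  }
  if (qr(M)$rank < ncol(M)) stop("design matrix is rank deficient")
  M
}
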