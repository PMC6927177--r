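
#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-bin model fit
#'
#' @param x a `merip_fit`
#' @param ... unused
#' @return tibble with one row per model term: `term`, `estimate`, plus
#'   `std.error`, `statistic`, `p.value` for the group term
#' @method tidy merip_fit
#' @export
tidy.merip_fit <- function(x, ...) {
  wt <- wald_test(x)
  tibble(term = c(names(x$coef), "psi"),
         estimate = c(unname(x$coef), x$psi),
         std.error = ifelse(names(c(x$coef, psi = 1)) == "group", wt$se, NA),
         statistic = ifelse(names(c(x$coef, psi = 1)) == "group",
                            wt$statistic, NA),
         p.value = ifelse(names(c(x$coef, psi = 1)) == "group",
                          wt$p.value, NA))
}

#' One-row fit summary
#' @param x a `merip_fit`
#' @param ... unused
#' @method glance merip_fit
#' @export
glance.merip_fit <- function(x, ...) {
  tibble(logLik = x$loglik, psi = x$psi, n_iter = x$n_iter,
         converged = x$converged, nobs = length(x$y))
}

#' @method tidy merip_dm
#' @export
tidy.merip_dm <- function(x, ...) {
  as_tibble(x)
}

#' Summary counts of a differential methylation run
#' @param x a `merip_dm` tibble
#' @param fdr_cutoff cutoff used for the significant-bin count
#' @param ... unused
#' @method glance merip_dm
#' @export
glance.merip_dm <- function(x, fdr_cutoff = 0.1, ...) {
  tibble(n_tested = nrow(x),
         n_converged = sum(x$converged),
         n_significant = sum(!is.na(x$padj) & x$padj < fdr_cutoff),
         fdr_cutoff = fdr_cutoff)
}
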