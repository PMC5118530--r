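#' Enumerate candidate SNP subsets
#'
#' All 2^s subsets of `snps` (including the empty/null model) in the
#' deterministic binary-counting order: subset k contains SNP j iff bit j of
#' k is set. Exhaustive search is capped at s = 20; larger panels must be
#' pre-screened (e.g. to the PS-selected SNPs).
#'
#' @param snps character vector of SNP ids.
#' @param cap hard cap on s (default 20).
#' @return List of character vectors; element 1 is the empty subset.
#' @export
enumerate_models <- function(snps, cap = 20) {
  s <- length(snps)
  if (s > cap) {
    stop("exhaustive enumeration capped at ", cap, " SNPs (2^", s,
         " models); pre-screen the panel (e.g. by PS) first")
  }
  lapply(0:(2^s - 1), function(k) snps[bitwAnd(k, bitwShiftL(1L, seq_len(s) - 1L)) != 0L])
}

#' Score every SNP-subset model for one trait (BQTN)
#'
#' Fits the covariates-only polygenic null once, then every subset model
#' (null covariates + the subset's dosage columns as fixed effects, polygenic
#' variance re-profiled per model) and scores each by
#' BIC_k = -Lambda_k0 + df_k * ln(N_e), with Lambda_k0 the LRT statistic of
#' model k against the null and df_k the number of SNP terms. The null model
#' scores Lambda = 0, BIC = 0 by construction, so negative BICs flag subsets
#' that beat the penalty.
#'
#' @inheritParams mga_scan
#' @param snps SNP ids forming the candidate panel (s <= 20).
#' @param n_e effective sample size for the penalty; `NULL` (default) uses
#'   the complete-case n, recorded in the report.
#' @param window_rule `"below_null"` (default: models with BIC < 0) or
#'   `"delta"` (BIC within `delta` of the best).
#' @param delta window width for `window_rule = "delta"`.
#' @return A list of class `"bqtn_report"`: `models` (data frame with
#'   model_id, snps, df, loglik, lambda, bic, weight, rank_deficient),
#'   `best`, `best_snp_p` (drop-one 1-df LRT p-values inside the best
#'   model), `h_r2` (polygenic fraction of the null model), `delta_bic`
#'   (best vs null), `window_n`, `n_e`, `n`, `trait`.
#' @export
bqtn_scan <- function(trait, genotypes, phenotypes, phi, snps, pcs = NULL,
                      trait_type = "auto", n_e = NULL,
                      window_rule = c("below_null", "delta"), delta = 2) {
  window_rule <- match.arg(window_rule)
  setup <- .scan_setup(trait, genotypes, phenotypes, phi, pcs, trait_type)
  subsets <- enumerate_models(snps)
  G <- setup$G[, snps, drop = FALSE]
  if (anyNA(G)) { # complete cases across the whole panel, fitted once
    ok <- stats::complete.cases(G)
    setup$y <- setup$y[ok]
    setup$X <- setup$X[ok, , drop = FALSE]
    G <- G[ok, , drop = FALSE]
    setup$rot <- .vc_rotation(setup$A[ok, ok], setup$X)
  }
  n_used <- length(setup$y)
  if (is.null(n_e)) n_e <- n_used
  yt <- crossprod(setup$rot$U, setup$y)
  Gt <- crossprod(setup$rot$U, G)
  null_fit <- .profile_gamma(yt, setup$rot$Xt, setup$rot$d)
  fit_subset <- function(sub) {
    if (!length(sub)) return(list(ll = null_fit$ll, rank_def = FALSE))
    Xt <- cbind(setup$rot$Xt, Gt[, sub, drop = FALSE])
    pr <- .profile_gamma(yt, Xt, setup$rot$d)
    rank_def <- qr(Xt)$rank < ncol(Xt)
    list(ll = pr$ll, rank_def = rank_def)
  }
  fits <- lapply(subsets, fit_subset)
  lls <- vapply(fits, `[[`, 0, "ll")
  lambda <- pmax(0, 2 * (lls - null_fit$ll))
  df_k <- lengths(subsets)
  bic <- -lambda + df_k * log(n_e)
  models <- data.frame(
    model_id = seq_along(subsets) - 1L,
    snps = vapply(subsets, paste, "", collapse = "+"),
    df = df_k, loglik = lls, lambda = lambda, bic = bic,
    rank_deficient = vapply(fits, `[[`, FALSE, "rank_def"),
    stringsAsFactors = FALSE)
  report <- select_best(models, window_rule = window_rule, delta = delta)
  best_sub <- subsets[[report$best_row]]
  best_snp_p <- stats::setNames(numeric(0), character(0))
  if (length(best_sub)) {
    ll_best <- lls[report$best_row]
    best_snp_p <- vapply(best_sub, function(s) {
      ll_m <- fit_subset(setdiff(best_sub, s))$ll
      stat <- max(0, 2 * (ll_best - ll_m))
      if (stat == 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
    }, 0)
  }
  structure(list(trait = trait, models = report$models,
                 best = report$models[report$best_row, ],
                 best_row = report$best_row,
                 best_snps = best_sub, best_snp_p = best_snp_p,
                 h_r2 = null_fit$gamma,
                 delta_bic = report$models$bic[report$best_row],
                 window_n = report$window_n, n_e = n_e, n = n_used,
                 trait_type = setup$type),
            class = "bqtn_report")
}

#' Select the best-BIC model and the model window
#'
#' Best = argmin BIC with deterministic tie-break (fewer SNPs, then
#' lexicographic SNP ids). The window counts models strictly better than the
#' null (BIC < 0) under the default rule, or within `delta` of the best.
#' BIC weights w_k proportional to exp(-BIC_k / 2) are normalized over all
#' candidates.
#'
#' @param models data frame with columns `snps`, `df`, `bic` (as produced by
#'   [bqtn_scan()]).
#' @param window_rule,delta see [bqtn_scan()].
#' @return List with `models` (weights added), `best_row`, `window_n`.
#' @export
select_best <- function(models, window_rule = c("below_null", "delta"),
                        delta = 2) {
  window_rule <- match.arg(window_rule)
  stopifnot(nrow(models) >= 1)
  ord <- order(models$bic, models$df, models$snps)
  best_row <- ord[1]
  w <- exp(-(models$bic - min(models$bic)) / 2)
  models$weight <- w / sum(w)
  window_n <- if (window_rule == "below_null") {
    sum(models$bic < 0)
  } else {
    sum(models$bic <= models$bic[best_row] + delta) - 1L
  }
  list(models = models, best_row = best_row, window_n = window_n)
}

#' @export
print.bqtn_report <- function(x, ...) {
  cat("BQTN report for", x$trait, "(", nrow(x$models), "models, N_e =",
      x$n_e, ")\n")
  cat("  polygenic h_r2 (null model):", signif(x$h_r2, 3), "\n")
  cat("  best model:", if (nzchar(x$best$snps)) x$best$snps else "<null>",
      " BIC vs null =", signif(x$delta_bic, 4), "\n")
  cat("  models in window:", x$window_n, "\n")
  if (length(x$best_snp_p)) {
    cat("  drop-one p:", paste(names(x$best_snp_p),
                               signif(x$best_snp_p, 3), sep = " = ",
                               collapse = ", "), "\n")
  }
  invisible(x)
}
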