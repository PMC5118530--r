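#' Locus-level variance-component gene burden test
#'
#' Fits the two-component model Omega = sigma2 (2*Phi h_r2 + 2*E h_geff2 +
#' I e2) against the Phi-only polygenic null by maximum likelihood and tests
#' h_geff2 = 0 with the boundary LRT, whose null distribution is the 1/2:1/2
#' mixture of a point mass at zero and chi-square with 1 df
#' ([mixture_p()]). The fixed effects reuse the full measured-genotype
#' covariate set (age terms, sex terms, ancestry PCs). The SE of h_geff2
#' comes from the observed information of the profile likelihood at the
#' optimum; at a boundary estimate (h_geff2 = 0) a one-sided curvature is
#' used and the result flagged.
#'
#' @inheritParams mga_scan
#' @param e_matrix empirical kinship matrix from [empirical_kinship()].
#' @param lambda_grid,cache passed to [fit_ml()] for the two-kernel fit.
#' @param se compute the standard error of h_geff2 (default TRUE; skipped in
#'   large calibration loops).
#' @param min_n minimum complete cases (default 50).
#' @return A list of class `"burden_result"`: `trait`, `snp_set`, `n`,
#'   `h_geff2`, `se`, `p`, `h_r2`, `e2`, `lrt_stat`, `boundary`,
#'   `converged`.
#' @export
burden_test <- function(trait, genotypes, phenotypes, phi, e_matrix,
                        pcs = NULL, trait_type = "auto",
                        lambda_grid = seq(0, 1, length.out = 21),
                        cache = NULL, se = TRUE, min_n = 50,
                        snp_set = "all") {
  setup <- .scan_setup(trait, genotypes, phenotypes, phi, pcs, trait_type)
  ids <- setup$ids
  if (length(ids) < min_n) stop("fewer than ", min_n, " complete cases")
  B <- 2 * unclass(e_matrix)[ids, ids]
  A <- setup$A
  offd <- upper.tri(A)
  if (stats::sd(B[offd]) > 0 &&
      stats::cor(A[offd], B[offd]) > 0.999) {
    stop("empirical kinship is confounded with pedigree kinship ",
         "(correlation > 0.999): h_geff2 is not identifiable")
  }
  model_null <- variance_model(setup$y, setup$X, list(A))
  model_full <- variance_model(setup$y, setup$X, list(A, B))
  fit_null <- fit_ml(model_null, cache = if (!is.null(cache)) cache$null else NULL)
  fit_full <- fit_ml(model_full, lambda_grid = lambda_grid,
                     cache = if (!is.null(cache)) cache$full else NULL)
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  p <- mixture_p(stat)
  h_geff2 <- unname(fit_full$fractions["h_geff2"])
  boundary <- h_geff2 < 1e-8
  se_val <- NA_real_
  if (se) {
    se_val <- .burden_se(setup$y, setup$X, A, B,
                         h_r2 = unname(fit_full$fractions["h_r2"]),
                         h_geff2 = h_geff2, boundary = boundary)
  }
  structure(list(trait = trait, snp_set = snp_set, n = length(ids),
                 h_geff2 = h_geff2, se = se_val, p = p,
                 h_r2 = unname(fit_full$fractions["h_r2"]),
                 e2 = unname(fit_full$fractions["e2"]),
                 h_r2_null = unname(fit_null$fractions["h_r2"]),
                 lrt_stat = stat, boundary = boundary,
                 converged = fit_full$converged && fit_null$converged,
                 trait_type = setup$type),
            class = "burden_result")
}

# Observed-information SE of h_geff2 from the profile log-likelihood in
# (h_r2, h_geff2) with beta and sigma2 profiled out. At the h_geff2 = 0
# boundary, a one-sided second difference (inward steps) is used; a flat or
# wrong-signed curvature yields SE = 0, flagged upstream via `boundary`.
.burden_se <- function(y, X, A, B, h_r2, h_geff2, boundary, h = 1e-3) {
  ll <- function(hr, hg) .vc_loglik_direct(y, X, list(A, B), c(hr, hg))
  if (boundary) {
    d2 <- (ll(h_r2, 2 * h) - 2 * ll(h_r2, h) + ll(h_r2, 0)) / h^2
    if (!is.finite(d2) || d2 >= 0) return(0)
    return(sqrt(-1 / d2))
  }
  hr <- min(max(h_r2, h), 1 - h_geff2 - 2 * h)
  hg <- min(max(h_geff2, h), 1 - hr - 2 * h)
  f <- function(a, b) ll(hr + a * h, hg + b * h)
  d2rr <- (f(1, 0) - 2 * f(0, 0) + f(-1, 0)) / h^2
  d2gg <- (f(0, 1) - 2 * f(0, 0) + f(0, -1)) / h^2
  d2rg <- (f(1, 1) - f(1, -1) - f(-1, 1) + f(-1, -1)) / (4 * h^2)
  info <- -matrix(c(d2rr, d2rg, d2rg, d2gg), 2, 2)
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || cov[2, 2] < 0) return(NA_real_)
  sqrt(cov[2, 2])
}

#' @export
print.burden_result <- function(x, ...) {
  cat("burden test:", x$trait, "| SNP set:", x$snp_set, "| n =", x$n, "\n")
  cat(sprintf("  h_geff2 = %.4f (SE %.4f)  p = %.4f%s\n",
              x$h_geff2, x$se, x$p,
              if (x$boundary) "  [boundary]" else ""))
  cat(sprintf("  h_r2 = %.4f  e2 = %.4f\n", x$h_r2, x$e2))
  invisible(x)
}

#' Burden tests across traits and SNP-set definitions
#'
#' Runs [burden_test()] for every (trait, SNP set) combination -- the SNP
#' sets typically being `all` SNPs, the `coding` variants, and a
#' most-significantly-associated (`msa`) list -- and formats one row per
#' combination. Empty or all-monomorphic resolved sets flag their rows and
#' the panel continues.
#'
#' @inheritParams burden_test
#' @param traits character vector of trait column names.
#' @param snp_sets named list of SNP-id vectors defining each empirical
#'   kinship matrix.
#' @return Data frame with columns trait, snp_set, n, h_geff2, se, p, h_r2,
#'   boundary, converged, note.
#' @export
burden_panel <- function(traits, genotypes, phenotypes, phi, snp_sets,
                         pcs = NULL, se = TRUE, min_n = 50) {
  if (is.null(pcs)) pcs <- genotype_pcs(genotypes)
  rows <- list()
  for (set_name in names(snp_sets)) {
    snps <- snp_sets[[set_name]]
    E <- tryCatch(empirical_kinship(genotypes, snps = snps),
                  error = function(e) e)
    for (tr in traits) {
      if (inherits(E, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, snp_set = set_name, n = NA_integer_,
          h_geff2 = NA_real_, se = NA_real_, p = NA_real_, h_r2 = NA_real_,
          boundary = NA, converged = FALSE, note = conditionMessage(E),
          stringsAsFactors = FALSE)
        next
      }
      res <- tryCatch(
        burden_test(tr, genotypes, phenotypes, phi, E, pcs = pcs,
                    se = se, min_n = min_n, snp_set = set_name),
        error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
        data.frame(trait = tr, snp_set = set_name, n = NA_integer_,
                   h_geff2 = NA_real_, se = NA_real_, p = NA_real_,
                   h_r2 = NA_real_, boundary = NA, converged = FALSE,
                   note = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        data.frame(trait = tr, snp_set = set_name, n = res$n,
                   h_geff2 = res$h_geff2, se = res$se, p = res$p,
                   h_r2 = res$h_r2, boundary = res$boundary,
                   converged = res$converged, note = "",
                   stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
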