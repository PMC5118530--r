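#' Rank-based inverse-normal transformation
#'
#' Blom transform: value i maps to qnorm((r_i - 3/8) / (n + 1/4)) with
#' average ranks for ties, giving an approximately N(0, 1) variable that is a
#' monotone function of the input ranks. Missing values stay missing.
#'
#' @param values numeric vector with at least 3 non-missing, non-constant
#'   values.
#' @return Numeric vector of z-scores.
#' @export
inverse_normalize <- function(values) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n < 3) stop("need at least 3 non-missing values")
  if (stats::var(values[obs]) == 0) stop("cannot inverse-normalize a constant vector")
  r <- rank(values[obs], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[obs] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Principal components of the dosage matrix
#'
#' Ancestry covariates: missing dosages are mean-imputed per SNP, columns are
#' standardized, and the top `k` left singular vectors (ordered by decreasing
#' eigenvalue) are returned as unit-norm score columns.
#'
#' @param genotypes a [genotype_matrix()].
#' @param k number of components (default 4).
#' @return n x k matrix with columns PC1..PCk and individual ids as rownames.
#' @export
genotype_pcs <- function(genotypes, k = 4) {
  G <- genotypes$dosage
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
  }
  sds <- apply(G, 2, stats::sd)
  G <- G[, sds > 0, drop = FALSE]
  if (ncol(G) < k) stop("fewer polymorphic SNPs than requested components")
  Gs <- scale(G)
  sv <- svd(Gs, nu = k, nv = 0)
  if (sum(sv$d > 1e-8) < k) stop("requested k exceeds the rank of the dosage matrix")
  scores <- sv$u[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(genotypes$dosage)
  scores
}

# The standard covariate design: intercept, age, age^2, sex and their
# interactions, plus ancestry PCs. Age terms are scaled for conditioning.
.covariate_matrix <- function(phenotypes, pcs = NULL) {
  age_s <- (phenotypes$age - 40) / 15
  female <- as.numeric(phenotypes$sex == 2L)
  X <- cbind(`(Intercept)` = 1, age = age_s, age2 = age_s^2, female = female,
             age_female = age_s * female, age2_female = age_s^2 * female)
  rownames(X) <- phenotypes$id
  if (!is.null(pcs)) X <- cbind(X, pcs[phenotypes$id, , drop = FALSE])
  X
}

# Resolve trait type: binary if the non-missing values are all 0/1.
.trait_type <- function(y, trait_type = c("auto", "quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  if (trait_type != "auto") return(trait_type)
  v <- unique(stats::na.omit(y))
  if (all(v %in% c(0, 1))) "binary" else "quantitative"
}

# Shared setup for the scan-type analyses: complete cases, transformed
# response, covariate design and the eigen-rotation of 2*Phi.
.scan_setup <- function(trait, genotypes, phenotypes, phi, pcs,
                        trait_type = "auto") {
  if (is.null(pcs)) pcs <- genotype_pcs(genotypes)
  y_all <- phenotypes[[trait]]
  if (is.null(y_all)) stop("trait not found in phenotype table: ", trait)
  type <- .trait_type(y_all, trait_type)
  X_all <- .covariate_matrix(phenotypes, pcs)
  ids <- phenotypes$id[!is.na(y_all) & stats::complete.cases(X_all)]
  ids <- ids[ids %in% rownames(genotypes$dosage) & ids %in% rownames(phi)]
  y <- y_all[match(ids, phenotypes$id)]
  if (type == "quantitative") y <- inverse_normalize(y)
  X <- X_all[ids, , drop = FALSE]
  A <- 2 * unclass(phi)[ids, ids]
  list(ids = ids, y = y, X = X, A = A, type = type,
       rot = .vc_rotation(A, X), G = genotypes$dosage[ids, , drop = FALSE])
}

# One dosage-term LRT given a prepared rotation: fit null (covariates only)
# and full (covariates + extra columns), return the pieces scans need.
.dosage_lrt <- function(setup, extra, null_fit = NULL) {
  yt <- crossprod(setup$rot$U, setup$y)
  if (is.null(null_fit)) {
    null_fit <- .profile_gamma(yt, setup$rot$Xt, setup$rot$d)
  }
  Et <- crossprod(setup$rot$U, extra)
  Xt_full <- cbind(setup$rot$Xt, Et)
  full <- .profile_gamma(yt, Xt_full, setup$rot$d)
  v <- full$gamma * setup$rot$d + (1 - full$gamma)
  at_opt <- .ll_diag(yt, Xt_full, v, want_fit = TRUE)
  stat <- max(0, 2 * (full$ll - null_fit$ll))
  p <- if (stat == 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
  k <- ncol(setup$rot$Xt) + ncol(extra)
  list(p = p, stat = stat,
       beta = at_opt$beta[k], se = at_opt$beta_se[k],
       ll_full = full$ll, ll_null = null_fit$ll, null_fit = null_fit,
       h2 = full$gamma)
}

#' Measured-genotype association scan
#'
#' For each SNP, fits the polygenic variance-components model with and
#' without the additive dosage term (all covariates -- age, age^2, sex,
#' age x sex, age^2 x sex and the top `k` ancestry PCs -- retained in both)
#' and reports the per-dosage effect B, its SE, and the 1-df likelihood-ratio
#' p-value. Continuous traits are inverse-normalized first, so B is in
#' transformed-trait SD units. SNPs monomorphic in the analyzed subset or
#' with fewer than `min_n` complete cases are skipped with a message.
#'
#' @param trait column name in `phenotypes`.
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a phenotype table with `id`, `age`, `sex` and the trait.
#' @param phi pedigree kinship matrix from [pedigree_kinship()].
#' @param pcs optional precomputed [genotype_pcs()] (computed if NULL).
#' @param trait_type `"auto"` (binary iff the values are 0/1),
#'   `"quantitative"` or `"binary"`; binary traits are analyzed as 0/1
#'   indicators in the Gaussian machinery.
#' @param snps optional subset of SNP ids to scan.
#' @param min_n minimum complete cases per SNP (default 30).
#' @param global_alpha global type-I error rate used for the Li-Ji corrected
#'   per-test threshold (default 0.05).
#' @return A data frame of class `"scan_result"` with columns snp, chrom,
#'   pos, maf, n, beta, se, p, neglog10p, and attributes `m_eff` (the
#'   [li_ji_meff()] result), `per_test_alpha`, `trait`, `trait_type`.
#' @export
mga_scan <- function(trait, genotypes, phenotypes, phi, pcs = NULL,
                     trait_type = "auto", snps = NULL, min_n = 30,
                     global_alpha = 0.05) {
  setup <- .scan_setup(trait, genotypes, phenotypes, phi, pcs, trait_type)
  snp_ids <- if (is.null(snps)) genotypes$snps$id else snps
  meta <- genotypes$snps[match(snp_ids, genotypes$snps$id), ]
  yt <- crossprod(setup$rot$U, setup$y)
  null_fit <- .profile_gamma(yt, setup$rot$Xt, setup$rot$d)
  res <- lapply(snp_ids, function(s) {
    g <- setup$G[, s]
    ok <- !is.na(g)
    na_row <- data.frame(snp = s, n = sum(ok), beta = NA_real_, se = NA_real_,
                         p = NA_real_, stringsAsFactors = FALSE)
    if (sum(ok) < min_n) {
      message("skipping ", s, ": fewer than ", min_n, " complete cases")
      return(na_row)
    }
    af <- mean(g[ok]) / 2
    if (af <= 0 || af >= 1) {
      message("skipping ", s, ": monomorphic in analyzed subset")
      return(na_row)
    }
    if (all(ok)) {
      out <- .dosage_lrt(setup, cbind(dosage = g), null_fit)
    } else {
      sub <- list(y = setup$y[ok], X = setup$X[ok, , drop = FALSE])
      sub$rot <- .vc_rotation(setup$A[ok, ok], sub$X)
      out <- .dosage_lrt(sub, cbind(dosage = g[ok]))
    }
    data.frame(snp = s, n = sum(ok), beta = unname(out$beta),
               se = unname(out$se), p = out$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- data.frame(snp = res$snp, chrom = meta$chrom, pos = meta$pos,
                    maf = meta$maf, n = res$n, beta = res$beta, se = res$se,
                    p = res$p, neglog10p = -log10(res$p),
                    stringsAsFactors = FALSE)
  analyzed <- res$snp[!is.na(res$p)]
  meff <- if (length(analyzed) >= 2) {
    li_ji_meff(abs(stats::cor(setup$G[, analyzed, drop = FALSE],
                              use = "pairwise.complete.obs")))
  } else {
    list(M = length(analyzed), m_eff = length(analyzed))
  }
  thr <- corrected_threshold(global_alpha, max(meff$m_eff, 1))
  structure(res, class = c("scan_result", "data.frame"),
            m_eff = meff, per_test_alpha = thr$alpha,
            global_alpha = global_alpha, trait = trait,
            trait_type = setup$type)
}

#' Effective number of independent tests (Li-Ji)
#'
#' From the eigenvalues lambda_i of the absolute inter-marker correlation
#' matrix, M_eff = floor( sum_i [ I(lambda_i >= 1) + (lambda_i -
#' floor(lambda_i)) ] ): an identity correlation gives M_eff = M, perfect LD
#' gives 1.
#'
#' @param dosage_correlation square symmetric correlation matrix with unit
#'   diagonal (absolute values are taken).
#' @return A list of class `"meff_result"`: `M`, `eigenvalues`, `m_eff_raw`,
#'   `m_eff`.
#' @export
li_ji_meff <- function(dosage_correlation) {
  C <- as.matrix(dosage_correlation)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8) {
    stop("dosage correlation must be square and symmetric")
  }
  if (max(abs(diag(C) - 1)) > 1e-6) stop("correlation matrix must have unit diagonal")
  lam <- eigen(abs(C), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  contrib <- as.numeric(lam >= 1) + (lam - floor(lam))
  raw <- sum(contrib)
  structure(list(M = nrow(C), eigenvalues = lam, m_eff_raw = raw,
                 m_eff = as.integer(floor(raw + 1e-9))),
            class = "meff_result")
}

#' Multiple-testing-corrected per-test threshold
#'
#' Bonferroni by default: per-test alpha = global alpha / M_eff (Sidak,
#' 1 - (1 - alpha)^(1/M_eff), behind the `method` flag), reported with its
#' -log10 value.
#'
#' @param global_alpha global type-I error rate in (0, 1).
#' @param m_eff effective number of independent tests (>= 1).
#' @param method `"bonferroni"` (default) or `"sidak"`.
#' @return List with `alpha` and `neglog10`.
#' @export
corrected_threshold <- function(global_alpha, m_eff,
                                method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  if (global_alpha <= 0 || global_alpha >= 1) stop("global_alpha must be in (0, 1)")
  if (m_eff < 1) stop("m_eff must be >= 1")
  alpha <- switch(method,
                  bonferroni = global_alpha / m_eff,
                  sidak = 1 - (1 - global_alpha)^(1 / m_eff))
  list(alpha = alpha, neglog10 = -log10(alpha), method = method, m_eff = m_eff)
}

#' Cross-trait probability score
#'
#' PS = sum over traits of -log10 p for each SNP, summarizing the strength
#' of association across the trait panel. Zero p-values are clipped to the
#' smallest representable positive double with a warning. The significance
#' threshold is a configurable preset (default 4.3010).
#'
#' @param pvalues matrix of p-values (SNPs x traits, rownames = SNP ids) or a
#'   named per-trait vector for a single SNP.
#' @param threshold PS significance threshold.
#' @return A data frame of class `"ps_result"` with columns snp, ps, flagged
#'   and the per-trait contributions as an attribute.
#' @export
ps_score <- function(pvalues, threshold = 4.3010) {
  if (is.vector(pvalues)) {
    pvalues <- matrix(pvalues, nrow = 1,
                      dimnames = list("snp", names(pvalues)))
  }
  P <- as.matrix(pvalues)
  if (any(P <= 0, na.rm = TRUE)) {
    warning("p-value(s) of 0 clipped to the smallest representable positive")
    P[P <= 0] <- .Machine$double.xmin
  }
  if (any(P > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  contrib <- -log10(P)
  ps <- rowSums(contrib, na.rm = TRUE)
  out <- data.frame(snp = rownames(P), ps = ps,
                    flagged = ps > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("ps_result", "data.frame"),
            contributions = contrib, threshold = threshold)
}

# Binary modifier column for interaction / subgroup analyses.
.modifier_values <- function(phenotypes, modifier = c("age45", "sex")) {
  modifier <- match.arg(modifier)
  switch(modifier,
         age45 = stats::setNames(as.numeric(phenotypes$age >= 45), phenotypes$id),
         sex = stats::setNames(as.numeric(phenotypes$sex == 2L), phenotypes$id))
}

#' Genotype-by-age / genotype-by-sex interaction scan
#'
#' Adds the dosage x modifier product to the measured-genotype model (the
#' modifier main effect and the dosage main effect are in both nested
#' models) and tests it with a 1-df LRT, as when constraining the
#' interaction coefficient to zero. Age is binarized at 45 years; sex is the
#' female indicator. The screen uses a liberal global alpha (default 0.2)
#' corrected by Li-Ji M_eff per trait. A scan with an empty modifier stratum
#' is skipped with a message rather than an error.
#'
#' @inheritParams mga_scan
#' @param modifier `"age45"` or `"sex"`.
#' @param global_alpha screening global type-I error rate (default 0.2).
#' @return A `"scan_result"`-style data frame with columns snp, n, n_stratum0,
#'   n_stratum1, beta_interaction, p, neglog10p; attributes as in
#'   [mga_scan()] plus `modifier`.
#' @export
interaction_scan <- function(trait, genotypes, phenotypes, phi,
                             modifier = c("age45", "sex"), pcs = NULL,
                             trait_type = "auto", snps = NULL, min_n = 30,
                             global_alpha = 0.2) {
  modifier <- match.arg(modifier)
  setup <- .scan_setup(trait, genotypes, phenotypes, phi, pcs, trait_type)
  mod <- .modifier_values(phenotypes, modifier)[setup$ids]
  n0 <- sum(mod == 0); n1 <- sum(mod == 1)
  snp_ids <- if (is.null(snps)) genotypes$snps$id else snps
  empty <- data.frame(snp = character(), n = integer(),
                      beta_interaction = numeric(), p = numeric(),
                      neglog10p = numeric(), stringsAsFactors = FALSE)
  if (n0 < min_n || n1 < min_n) {
    message("interaction scan skipped: modifier stratum below ", min_n,
            " complete cases (", n0, " / ", n1, ")")
    return(structure(empty, class = c("scan_result", "data.frame"),
                     modifier = modifier, trait = trait, skipped = TRUE))
  }
  # modifier main effect joins the base design of both nested models
  setup_m <- setup
  setup_m$X <- cbind(setup$X, modifier = mod)
  setup_m$rot <- list(U = setup$rot$U, d = setup$rot$d,
                      Xt = cbind(setup$rot$Xt,
                                 modifier = drop(crossprod(setup$rot$U, mod))))
  res <- lapply(snp_ids, function(s) {
    g <- setup$G[, s]
    ok <- !is.na(g)
    if (sum(ok) < min_n || stats::var(g[ok]) == 0) {
      return(data.frame(snp = s, n = sum(ok), beta_interaction = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    if (all(ok)) {
      su <- setup_m
      gg <- g; mm <- mod
    } else {
      su <- list(y = setup$y[ok], X = setup_m$X[ok, , drop = FALSE])
      su$rot <- .vc_rotation(setup$A[ok, ok], su$X)
      gg <- g[ok]; mm <- mod[ok]
    }
    # null: + dosage; full: + dosage + dosage x modifier
    gt <- drop(crossprod(su$rot$U, gg))
    su_null <- su
    su_null$rot$Xt <- cbind(su$rot$Xt, dosage = gt)
    out <- .dosage_lrt(su_null, cbind(dosage_x_mod = gg * mm))
    data.frame(snp = s, n = length(gg), beta_interaction = unname(out$beta),
               p = out$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$neglog10p <- -log10(res$p)
  analyzed <- res$snp[!is.na(res$p)]
  meff <- if (length(analyzed) >= 2) {
    li_ji_meff(abs(stats::cor(setup$G[, analyzed, drop = FALSE],
                              use = "pairwise.complete.obs")))
  } else {
    list(M = length(analyzed), m_eff = length(analyzed))
  }
  thr <- corrected_threshold(global_alpha, max(meff$m_eff, 1))
  structure(res, class = c("scan_result", "data.frame"),
            m_eff = meff, per_test_alpha = thr$alpha,
            global_alpha = global_alpha, trait = trait,
            trait_type = setup$type, modifier = modifier,
            n_strata = c(n0, n1), skipped = FALSE)
}

#' Measured-genotype fit within a modifier stratum
#'
#' Refits the single-SNP measured-genotype model inside one level of the
#' binarized modifier (or the full sample when `modifier` is NULL) and
#' reports the stratum effect B, n and p -- the subgroup-analysis companion
#' to [interaction_scan()].
#'
#' @inheritParams interaction_scan
#' @param snp single SNP id.
#' @param level modifier level (0 or 1) defining the stratum.
#' @return List with `snp`, `modifier`, `level`, `n`, `beta`, `se`, `p`.
#' @export
subgroup_fit <- function(trait, snp, genotypes, phenotypes, phi,
                         modifier = NULL, level = 1, pcs = NULL,
                         trait_type = "auto", min_n = 30) {
  if (is.null(pcs)) pcs <- genotype_pcs(genotypes)
  keep <- rep(TRUE, nrow(phenotypes))
  if (!is.null(modifier)) {
    keep <- .modifier_values(phenotypes, modifier) == level
  }
  ph <- phenotypes[keep, , drop = FALSE]
  if (nrow(ph) < min_n) {
    return(list(snp = snp, modifier = modifier, level = level,
                n = nrow(ph), beta = NA_real_, se = NA_real_, p = NA_real_,
                skipped = TRUE))
  }
  scan <- mga_scan(trait, genotypes, ph, phi, pcs = pcs,
                   trait_type = trait_type, snps = snp, min_n = min_n)
  list(snp = snp, modifier = modifier, level = level,
       n = scan$n[1], beta = scan$beta[1], se = scan$se[1], p = scan$p[1],
       skipped = FALSE)
}

#' Manhattan-style plot of a scan
#'
#' -log10 p against locus position, with the Li-Ji corrected per-test
#' threshold as a horizontal reference line.
#'
#' @param x a `"scan_result"` from [mga_scan()].
#' @param ... passed to [plot()].
#' @export
plot.scan_result <- function(x, ...) {
  thr <- attr(x, "per_test_alpha")
  graphics::plot(x$pos / 1e6, x$neglog10p, pch = 19, cex = 0.6,
                 xlab = "position (Mb)", ylab = expression(-log[10] * p), ...)
  if (!is.null(thr)) graphics::abline(h = -log10(thr), lty = 2, col = "red3")
  invisible(x)
}
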