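#' Null-calibration simulation for the scan-level tests
#'
#' Simulates traits with no SNP effect (and, for the burden kind, no
#' gene-specific variance component) on a fixed synthetic pedigree/genotype
#' panel and measures the empirical type-I error of the measured-genotype
#' LRT, the genotype-by-age interaction LRT, or the burden mixture test at
#' level `alpha`. The pedigree, genotypes, covariates and every
#' eigendecomposition are computed once and reused across replicates (the
#' fast path), so thousands of replicates run in seconds to minutes.
#' The fitting routines exercised are the same internals used by
#' [mga_scan()], [interaction_scan()] and [burden_test()].
#'
#' @param kind which test to calibrate.
#' @param n_reps number of simulated null replicates.
#' @param alpha nominal level.
#' @param n_pedigrees number of families (default 18, about 600 individuals
#'   with the default template).
#' @param n_snps SNPs at the simulated locus (default 118, the emulated
#'   locus size; small panels leave the gene-specific component weakly
#'   identified and the burden mixture test finite-sample conservative).
#' @param h2 polygenic heritability of the simulated trait.
#' @param beta_g main dosage effect shared by both modifier strata in the
#'   interaction null (the interaction term itself is zero).
#' @param seed integer seed.
#' @param lambda_grid mixing-weight grid for the burden two-kernel fits
#'   (log-spaced near zero, where the boundary overfit bump lives).
#' @return List with `type1`, its Monte-Carlo `se`, the vector of `pvalues`,
#'   `n` (individuals) and `kind`.
#' @export
null_calibration <- function(kind = c("mga", "interaction", "burden"),
                             n_reps = 2000, alpha = 0.05, n_pedigrees = 18,
                             n_snps = 118, h2 = 0.4, beta_g = 0.2, seed = 1,
                             lambda_grid = c(0, 10^seq(-3, -1, length.out = 6),
                                             seq(0.15, 1, by = 0.05))) {
  kind <- match.arg(kind)
  cfg <- sim_config(n_pedigrees = n_pedigrees, n_snps = n_snps, seed = seed)
  ped <- simulate_pedigrees(cfg)
  geno <- simulate_genotypes(ped, cfg)
  phi <- pedigree_kinship(ped)
  phen <- simulate_traits(ped, geno, phi, cfg)
  # the emulated study's admixture PCs are genome-wide covariates; the
  # synthetic cohort is ancestrally homogeneous and PCs computed from the
  # locus itself would interact with the locus terms under test (they span
  # E's top eigen-directions and load on every locus dosage; see vignette),
  # so the calibration designs carry the age/sex covariate set only
  X <- .covariate_matrix(phen)
  A <- 2 * unclass(phi)
  blocks <- polygenic_chol(ped, phi)
  n <- nrow(ped)
  m <- ncol(geno$dosage)
  G <- geno$dosage
  set.seed(seed + 11L)
  draw_y <- function(extra = 0) {
    g <- numeric(n)
    for (b in blocks) g[b$idx] <- crossprod(b$L, stats::rnorm(length(b$idx)))
    extra + sqrt(h2) * g + stats::rnorm(n, sd = sqrt(1 - h2))
  }
  pvals <- numeric(n_reps)
  if (kind == "mga") {
    rot <- .vc_rotation(A, X)
    Gt <- crossprod(rot$U, G)
    for (r in seq_len(n_reps)) {
      y <- draw_y()
      yt <- crossprod(rot$U, y)
      ll0 <- .profile_gamma(yt, rot$Xt, rot$d)$ll
      j <- (r - 1L) %% m + 1L
      ll1 <- .profile_gamma(yt, cbind(rot$Xt, Gt[, j]), rot$d)$ll
      stat <- max(0, 2 * (ll1 - ll0))
      pvals[r] <- if (stat == 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
    }
  } else if (kind == "interaction") {
    mod <- as.numeric(phen$age >= 45)
    Xm <- cbind(X, modifier = mod)
    rot <- .vc_rotation(A, Xm)
    Gt <- crossprod(rot$U, G)
    Pt <- crossprod(rot$U, G * mod)
    for (r in seq_len(n_reps)) {
      j <- (r - 1L) %% m + 1L
      y <- draw_y(extra = beta_g * G[, j]) # same effect in both strata
      yt <- crossprod(rot$U, y)
      ll0 <- .profile_gamma(yt, cbind(rot$Xt, Gt[, j]), rot$d)$ll
      ll1 <- .profile_gamma(yt, cbind(rot$Xt, Gt[, j], Pt[, j]), rot$d)$ll
      stat <- max(0, 2 * (ll1 - ll0))
      pvals[r] <- if (stat == 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
    }
  } else {
    E <- empirical_kinship(geno)
    B <- 2 * unclass(E)
    # ancestry PCs are genome-wide covariates in the emulated study; PCs
    # computed from the locus itself span E's top eigen-directions and
    # would absorb the very signal the burden test probes (see vignette),
    # so the homogeneous-ancestry burden null is fitted without them
    Xb <- .covariate_matrix(phen)
    rot0 <- .vc_rotation(A, Xb)
    rots <- lapply(lambda_grid, function(lam) {
      .vc_rotation((1 - lam) * A + lam * B, Xb)
    })
    for (r in seq_len(n_reps)) {
      y <- draw_y()
      ll0 <- .profile_gamma(crossprod(rot0$U, y), rot0$Xt, rot0$d)$ll
      ll1 <- max(vapply(rots, function(rt) {
        .profile_gamma(crossprod(rt$U, y), rt$Xt, rt$d)$ll
      }, 0))
      pvals[r] <- mixture_p(max(0, 2 * (ll1 - ll0)))
    }
  }
  type1 <- mean(pvals <= alpha)
  list(kind = kind, type1 = type1,
       se = sqrt(alpha * (1 - alpha) / n_reps),
       pvalues = pvals, n = n, n_reps = n_reps, alpha = alpha)
}

#' Parameter-recovery simulation for the variance-components estimators
#'
#' `kind = "h2"`: simulates pedigree traits with polygenic heritability `h2`
#' and refits the single-kernel model, reporting the mean estimate across
#' replicates. `kind = "h_geff2"`: simulates traits carrying both a
#' polygenic fraction `h_r2` (kernel 2*Phi) and a gene-specific fraction
#' `h_geff2` (kernel 2*E from the simulated locus) and refits the
#' two-kernel model on a fixed mixing-weight grid.
#'
#' @param kind which estimator to probe.
#' @param n_reps replicates (default 200).
#' @param n_pedigrees families (defaults give about 1,200 individuals for
#'   `"h2"` and 1,300 for `"h_geff2"`).
#' @param h2 true polygenic fraction for `kind = "h2"`.
#' @param h_r2,h_geff2 true fractions for `kind = "h_geff2"`.
#' @param n_snps SNPs at the simulated locus (E-matrix kinds only).
#' @param seed integer seed.
#' @param lambda_grid mixing-weight grid for two-kernel fits.
#' @return List with `mean`, `estimates`, `target`, `n`.
#' @export
recovery_simulation <- function(kind = c("h2", "h_geff2"), n_reps = 200,
                                n_pedigrees = if (match.arg(kind) == "h2") 36 else 38,
                                h2 = 0.4, h_r2 = 0.30, h_geff2 = 0.10,
                                n_snps = 118, seed = 1,
                                lambda_grid = seq(0, 1, length.out = 21)) {
  kind <- match.arg(kind)
  cfg <- sim_config(n_pedigrees = n_pedigrees, n_snps = n_snps, seed = seed)
  ped <- simulate_pedigrees(cfg)
  phi <- pedigree_kinship(ped)
  phen_stub <- simulate_traits(ped, NULL, phi, cfg)
  X <- .covariate_matrix(phen_stub) # no PCs: ancestry is homogeneous here
  A <- 2 * unclass(phi)
  blocks <- polygenic_chol(ped, phi)
  n <- nrow(ped)
  set.seed(seed + 13L)
  draw_g <- function() {
    g <- numeric(n)
    for (b in blocks) g[b$idx] <- crossprod(b$L, stats::rnorm(length(b$idx)))
    g
  }
  est <- numeric(n_reps)
  if (kind == "h2") {
    rot <- .vc_rotation(A, X)
    for (r in seq_len(n_reps)) {
      y <- sqrt(h2) * draw_g() + stats::rnorm(n, sd = sqrt(1 - h2))
      est[r] <- .profile_gamma(crossprod(rot$U, y), rot$Xt, rot$d)$gamma
    }
    target <- h2
  } else {
    geno <- simulate_genotypes(ped, cfg)
    E <- empirical_kinship(geno)
    B <- 2 * unclass(E)
    LB <- chol(B + diag(1e-8, n))
    rots <- lapply(lambda_grid, function(lam) {
      .vc_rotation((1 - lam) * A + lam * B, X)
    })
    e2 <- 1 - h_r2 - h_geff2
    for (r in seq_len(n_reps)) {
      y <- sqrt(h_r2) * draw_g() +
        sqrt(h_geff2) * drop(crossprod(LB, stats::rnorm(n))) +
        stats::rnorm(n, sd = sqrt(e2))
      prs <- lapply(rots, function(rt) {
        .profile_gamma(crossprod(rt$U, y), rt$Xt, rt$d)
      })
      i <- which.max(vapply(prs, `[[`, 0, "ll"))
      est[r] <- prs[[i]]$gamma * lambda_grid[i]
    }
    target <- h_geff2
  }
  list(kind = kind, mean = mean(est), estimates = est, target = target,
       n = n, n_reps = n_reps)
}
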