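# Shared fixtures and independent oracles. Everything is generated in code;
# datasets are memoised so several test files can reuse one simulation.

.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function(key = "default", n_pedigrees = 6, n_snps = 30,
                            seed = 1, ...) {
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- sim_config(n_pedigrees = n_pedigrees, n_snps = n_snps, seed = seed, ...)
  ped <- simulate_pedigrees(cfg)
  geno <- simulate_genotypes(ped, cfg)
  phi <- pedigree_kinship(ped)
  phen <- simulate_traits(ped, geno, phi, cfg)
  res <- list(cfg = cfg, ped = ped, geno = geno, phi = phi, phen = phen,
              pcs = genotype_pcs(geno))
  assign(key, res, envir = .fixture_env)
  res
}

# Six-member pedigree with known kinship: founders a, b, e; c and d are full
# sibs (a x b); f is their paternal half sib (a x e).
hand_pedigree <- function() {
  pedigree(fam = "f1",
           id = c("a", "b", "e", "c", "d", "f"),
           father = c(NA, NA, NA, "a", "a", "a"),
           mother = c(NA, NA, NA, "b", "b", "e"),
           sex = c(1, 2, 2, 1, 2, 1))
}

# Monte-Carlo gene-dropping kinship oracle, independent of the recursion:
# founders get unique allele labels, alleles drop with fair coin flips, and
# phi_ij is estimated as the probability that randomly chosen alleles from i
# and j are identical by descent (averaged over the four allele pairings).
gene_drop_phi <- function(ped, n_drops = 20000) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  ord <- order(famvc::pedigree_depth(ped), seq_len(n))
  H1 <- matrix(0L, n_drops, n)
  H2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(fa[i])) {
      H1[, i] <- lab + 1L
      H2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick1 <- stats::runif(n_drops) < 0.5
      pick2 <- stats::runif(n_drops) < 0.5
      H1[, i] <- ifelse(pick1, H1[, fa[i]], H2[, fa[i]])
      H2[, i] <- ifelse(pick2, H1[, mo[i]], H2[, mo[i]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (H1[, i] == H1[, j]) + (H1[, i] == H2[, j]) +
        (H2[, i] == H1[, j]) + (H2[, i] == H2[, j])
      phi[i, j] <- phi[j, i] <- mean(ibd) / 4
    }
  }
  phi
}

# Independent ML profile log-likelihood: explicit inverse and determinant,
# no rotations -- the brute-force oracle for the eigen fast path.
oracle_loglik <- function(y, X, V0) {
  Vi <- solve(V0)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  n <- length(y)
  s2 <- drop(t(r) %*% Vi %*% r) / n
  ld <- as.numeric(determinant(V0, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + n * log(s2) + ld + n)
}

# Small power/calibration loop sharing the cached-rotation approach of the
# package's calibration harness but driven from test code.
simulate_scan_pvalues <- function(d, n_reps, beta_snp = 0, h2 = 0.4,
                                  interaction_beta = NULL, seed = 99,
                                  snp = NULL) {
  # ancestry PCs are genome-wide covariates in the emulated design; PCs of
  # the locus itself would absorb part of the planted dosage effect
  X <- famvc:::.covariate_matrix(d$phen)
  A <- 2 * unclass(d$phi)
  blocks <- famvc:::polygenic_chol(d$ped, d$phi)
  G <- d$geno$dosage
  m <- ncol(G)
  n <- nrow(G)
  set.seed(seed)
  if (is.null(interaction_beta)) {
    rot <- famvc:::.vc_rotation(A, X)
    Gt <- crossprod(rot$U, G)
  } else {
    mod <- as.numeric(d$phen$age >= 45)
    Xm <- cbind(X, modifier = mod)
    rot <- famvc:::.vc_rotation(A, Xm)
    Gt <- crossprod(rot$U, G)
    Pt <- crossprod(rot$U, G * mod)
  }
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    j <- if (is.null(snp)) (r - 1L) %% m + 1L else match(snp, colnames(G))
    g <- numeric(n)
    for (b in blocks) g[b$idx] <- crossprod(b$L, stats::rnorm(length(b$idx)))
    if (is.null(interaction_beta)) {
      y <- beta_snp * G[, j] + sqrt(h2) * g + stats::rnorm(n, sd = sqrt(1 - h2))
      yt <- crossprod(rot$U, y)
      ll0 <- famvc:::.profile_gamma(yt, rot$Xt, rot$d)$ll
      ll1 <- famvc:::.profile_gamma(yt, cbind(rot$Xt, Gt[, j]), rot$d)$ll
    } else {
      y <- beta_snp * G[, j] + interaction_beta * G[, j] * mod +
        sqrt(h2) * g + stats::rnorm(n, sd = sqrt(1 - h2))
      yt <- crossprod(rot$U, y)
      ll0 <- famvc:::.profile_gamma(yt, cbind(rot$Xt, Gt[, j]), rot$d)$ll
      ll1 <- famvc:::.profile_gamma(yt, cbind(rot$Xt, Gt[, j], Pt[, j]), rot$d)$ll
    }
    stat <- max(0, 2 * (ll1 - ll0))
    pvals[r] <- if (stat == 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  pvals
}
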