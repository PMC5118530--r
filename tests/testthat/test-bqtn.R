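test_that("model enumeration: counts, balance, determinism, cap", {
  expect_length(enumerate_models(paste0("s", 1:11)), 2048L)
  expect_identical(enumerate_models(character(0)), list(character(0)))
  subs <- enumerate_models(c("a", "b", "c"))
  expect_length(subs, 8L)
  counts <- table(unlist(subs))
  expect_true(all(counts == 4L)) # each SNP in exactly half the subsets
  expect_identical(subs, enumerate_models(c("a", "b", "c")))
  expect_error(enumerate_models(paste0("s", 1:21)), "capped")
})

test_that("BQTN scores match independent per-model refits (s = 2)", {
  d <- fixture_dataset()
  snps <- d$geno$snps$id[c(2, 17)] # different LD blocks
  rep2 <- bqtn_scan("fasting_glucose", d$geno, d$phen, d$phi, snps = snps,
                    pcs = d$pcs)
  expect_equal(nrow(rep2$models), 4L)
  expect_equal(rep2$models$bic[1], 0) # null scores BIC = 0 by construction

  # independent route: refit each of the 4 models by explicit-inverse
  # likelihood over a dense h2 grid, then rebuild Lambda and BIC
  setup <- famvc:::.scan_setup("fasting_glucose", d$geno, d$phen, d$phi,
                               d$pcs, "auto")
  hs <- seq(0, 0.999, by = 0.002)
  refit <- function(sub) {
    Xs <- cbind(setup$X, setup$G[, sub, drop = FALSE])
    max(vapply(hs, function(h) {
      oracle_loglik(setup$y, Xs, h * setup$A + (1 - h) * diag(nrow(setup$A)))
    }, 0))
  }
  ll0 <- refit(character(0))
  for (k in seq_len(4)) {
    sub <- enumerate_models(snps)[[k]]
    lam_oracle <- max(0, 2 * (refit(sub) - ll0))
    expect_equal(rep2$models$lambda[k], lam_oracle, tolerance = 2e-3)
    expect_equal(rep2$models$bic[k],
                 -lam_oracle + length(sub) * log(rep2$n_e), tolerance = 2e-3)
  }
  # exhaustiveness: reported best is the enumerated minimum
  expect_equal(rep2$best$bic, min(rep2$models$bic))
  expect_equal(sum(rep2$models$weight), 1, tolerance = 1e-12)
})

test_that("null-SNP BIC centers on ln(N_e) - 1", {
  d <- fixture_dataset("calib", n_pedigrees = 18, n_snps = 24, seed = 51,
                       ld_block_size = 8)
  X <- famvc:::.covariate_matrix(d$phen, d$pcs)
  A <- 2 * unclass(d$phi)
  rot <- famvc:::.vc_rotation(A, X)
  blocks <- famvc:::polygenic_chol(d$ped, d$phi)
  G <- d$geno$dosage
  set.seed(77)
  n_e <- 1000
  bics <- vapply(1:150, function(r) {
    g <- numeric(nrow(G))
    for (b in blocks) g[b$idx] <- crossprod(b$L, stats::rnorm(length(b$idx)))
    y <- sqrt(0.4) * g + stats::rnorm(nrow(G), sd = sqrt(0.6))
    yt <- crossprod(rot$U, y)
    ll0 <- famvc:::.profile_gamma(yt, rot$Xt, rot$d)$ll
    j <- (r - 1L) %% ncol(G) + 1L
    ll1 <- famvc:::.profile_gamma(yt, cbind(rot$Xt, crossprod(rot$U, G[, j])),
                                  rot$d)$ll
    -max(0, 2 * (ll1 - ll0)) + log(n_e)
  }, 0)
  # E[Lambda] = 1 under the null, so E[BIC] ~ ln(1000) - 1 = 5.908
  expect_lt(abs(mean(bics) - (log(n_e) - 1)), 0.5)
})

test_that("select_best: tie-breaks, window rules, weights", {
  models <- data.frame(
    snps = c("", "a", "b", "a+b"),
    df = c(0L, 1L, 1L, 2L),
    bic = c(0, -1.5, -1.5, 2))
  out <- select_best(models)
  expect_equal(out$best_row, 2L) # tie broken lexicographically ("a" < "b")
  expect_equal(out$window_n, 2L) # both single-SNP models beat the null
  expect_equal(sum(out$models$weight), 1)
  # penalty-dominated case mirrors the all-null pattern: best = null model
  models2 <- data.frame(snps = c("", "a"), df = c(0L, 1L), bic = c(0, 5))
  out2 <- select_best(models2)
  expect_equal(out2$best_row, 1L)
  expect_equal(out2$window_n, 0L)
  # delta-window alternative
  expect_equal(select_best(models, window_rule = "delta", delta = 4)$window_n, 3L)
})

test_that("a strong planted QTN is recovered as the best model", {
  d <- fixture_dataset("calib", n_pedigrees = 18, n_snps = 24, seed = 51,
                       ld_block_size = 8)
  # one common SNP per LD block so the causal variant can win its block
  meta <- d$geno$snps
  panel <- vapply(split(seq_len(nrow(meta)), meta$block), function(i) {
    meta$id[i][which.max(meta$maf[i])]
  }, "")
  target <- panel[which.max(meta$maf[match(panel, meta$id)])]
  X <- famvc:::.covariate_matrix(d$phen, d$pcs)
  blocks <- famvc:::polygenic_chol(d$ped, d$phi)
  set.seed(91)
  hits <- 0L
  n_reps <- 12L
  for (r in seq_len(n_reps)) {
    g <- numeric(nrow(d$ped))
    for (b in blocks) g[b$idx] <- crossprod(b$L, stats::rnorm(length(b$idx)))
    ph <- d$phen
    ph$ytrait <- 0.5 * d$geno$dosage[, target] + sqrt(0.4) * g +
      stats::rnorm(nrow(d$ped), sd = sqrt(0.6))
    rep_r <- bqtn_scan("ytrait", d$geno, ph, d$phi, snps = panel, pcs = d$pcs)
    if (target %in% rep_r$best_snps) hits <- hits + 1L
  }
  expect_gte(hits, n_reps - 1L)
})

test_that("drop-one p-values inside the best model are 1-df LRTs", {
  d <- fixture_dataset()
  snps <- d$geno$snps$id[c(2, 17)]
  rep2 <- bqtn_scan("fasting_glucose", d$geno, d$phen, d$phi, snps = snps,
                    pcs = d$pcs)
  if (length(rep2$best_snps)) {
    expect_true(all(rep2$best_snp_p > 0 & rep2$best_snp_p <= 1))
    expect_named(rep2$best_snp_p, rep2$best_snps)
  } else {
    expect_length(rep2$best_snp_p, 0L)
  }
})
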