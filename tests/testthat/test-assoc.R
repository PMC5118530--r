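test_that("inverse normalization follows the Blom formula", {
  # hand evaluation at n = 3: ranks (1, 3, 2) -> quantiles (.1923, .8077, .5)
  z <- inverse_normalize(c(1, 5, 2))
  expect_equal(z, stats::qnorm(c(0.625, 2.625, 1.625) / 3.25), tolerance = 1e-12)
  expect_equal(z[1], -0.8694, tolerance = 1e-4)
  expect_equal(z[3], 0)

  set.seed(4)
  x <- stats::rexp(500)
  x[c(5, 50)] <- NA
  z <- inverse_normalize(x)
  expect_true(all(is.na(z[c(5, 50)])))
  obs <- !is.na(z)
  expect_lt(abs(mean(z[obs])), 1e-8)
  expect_lt(abs(stats::sd(z[obs]) - 1), 1e-2)
  # monotone in the input ranks
  expect_equal(order(z[obs]), order(x[obs]))
  # ties share averaged ranks
  zt <- inverse_normalize(c(1, 1, 2))
  expect_equal(zt[1], zt[2])
  expect_error(inverse_normalize(rep(3, 10)), "constant")
  expect_error(inverse_normalize(c(1, 2)), "at least 3")
})

test_that("genotype PCs capture admixture and meet the dimension contract", {
  set.seed(6)
  n <- 100; m <- 20
  pop <- rep(0:1, each = n / 2)
  p <- ifelse(outer(pop, rep(1, m)) == 1, 0.85, 0.15)
  G <- matrix(stats::rbinom(n * m, 2, p), n, m,
              dimnames = list(paste0("i", 1:n), paste0("s", 1:m)))
  G <- rbind(G, i999 = G[1, ])
  rownames(G)[n + 1] <- "i999"
  g <- genotype_matrix(G)
  pcs <- genotype_pcs(g, k = 4)
  expect_equal(dim(pcs), c(n + 1L, 4L))
  expect_gt(abs(stats::cor(pcs[1:n, 1], pop)), 0.9)
  # duplicated individual gets identical scores
  expect_equal(pcs["i999", ], pcs["i1", ], tolerance = 1e-10)
  expect_error(genotype_pcs(g, k = 50), "fewer|rank")
})

test_that("Li-Ji M_eff: identity, perfect LD, and the block closed form", {
  expect_equal(li_ji_meff(diag(10))$m_eff, 10L)
  expect_equal(li_ji_meff(matrix(1, 10, 10))$m_eff, 1L)
  # two independent exchangeable blocks of 5 with rho = 0.9:
  # eigenvalues are 1 + 4*rho (x2) and 1 - rho (x8), so
  # M_eff = 2*(1 + 0.6) + 8*0.1 = 4.0 by the closed form
  blk <- function(rho) (1 - rho) * diag(5) + rho
  C <- rbind(cbind(blk(0.9), matrix(0, 5, 5)),
             cbind(matrix(0, 5, 5), blk(0.9)))
  res <- li_ji_meff(C)
  expect_equal(res$m_eff_raw, 4.0, tolerance = 1e-10)
  expect_equal(res$m_eff, 4L)
  expect_error(li_ji_meff(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")

  # monotonicity on exchangeable families: more LD, never more tests
  meffs <- vapply(seq(0, 0.9, by = 0.1), function(r) {
    li_ji_meff((1 - r) * diag(10) + r)$m_eff_raw
  }, 0)
  expect_true(all(diff(meffs) <= 1e-9))
})

test_that("corrected thresholds: Bonferroni arithmetic and Sidak flag", {
  thr <- corrected_threshold(0.05, 49)
  expect_equal(thr$alpha, 0.05 / 49)
  expect_equal(round(thr$neglog10, 2), 2.99)
  expect_equal(corrected_threshold(0.2, 49)$alpha, 0.2 / 49) # ~0.00408
  expect_equal(corrected_threshold(0.37, 1)$alpha, 0.37)
  sid <- corrected_threshold(0.05, 49, method = "sidak")
  expect_equal(sid$alpha, 1 - 0.95^(1 / 49))
  expect_error(corrected_threshold(0.05, 0), "m_eff")
  expect_error(corrected_threshold(1.2, 10), "global_alpha")
})

test_that("PS score: floors, additivity, flagging, zero-p clipping", {
  p8 <- stats::setNames(rep(0.1, 8), paste0("t", 1:8))
  expect_equal(ps_score(p8)$ps, 8)
  expect_equal(ps_score(stats::setNames(rep(1, 8), paste0("t", 1:8)))$ps, 0)
  P <- matrix(stats::runif(40, 0.001, 1), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:4)))
  full <- ps_score(P)
  part <- ps_score(P[, 1:2])$ps + ps_score(P[, 3:4])$ps
  expect_equal(full$ps, part, tolerance = 1e-12)
  expect_equal(full$flagged, full$ps > 4.3010)
  expect_warning(psz <- ps_score(cbind(t1 = c(a = 0))), "clipped")
  expect_true(is.finite(psz$ps))
  expect_error(ps_score(c(t1 = 1.5)), "0, 1")
})

test_that("MGA scan: skips, allele-flip equivariance, OLS limit", {
  d <- fixture_dataset()
  scan <- mga_scan("fasting_glucose", d$geno, d$phen, d$phi, pcs = d$pcs)
  expect_s3_class(scan, "scan_result")
  expect_true(all(scan$p > 0 & scan$p <= 1, na.rm = TRUE))
  expect_equal(scan$neglog10p, -log10(scan$p), tolerance = 1e-10)
  expect_true(attr(scan, "m_eff")$m_eff <= nrow(scan))

  # allele flip: B changes sign, p unchanged
  s <- scan$snp[which.min(scan$p)]
  gf <- d$geno
  gf$dosage[, s] <- 2 - gf$dosage[, s]
  gf <- genotype_matrix(gf$dosage, gf$snps[, c("id", "chrom", "pos", "coding")])
  flip <- mga_scan("fasting_glucose", gf, d$phen, d$phi, pcs = d$pcs, snps = s)
  expect_equal(flip$beta[1], -scan$beta[scan$snp == s], tolerance = 1e-6)
  expect_equal(flip$p[1], scan$p[scan$snp == s], tolerance = 1e-6)

  # min_n guard skips with a message
  expect_message(
    small <- mga_scan("fasting_glucose", d$geno, d$phen, d$phi, pcs = d$pcs,
                      min_n = 1e6),
    "fewer than")
  expect_true(all(is.na(small$p)))
})

test_that("MGA has power against a planted additive effect", {
  d <- fixture_dataset("power", n_pedigrees = 38, n_snps = 24, seed = 51,
                       ld_block_size = 8)
  # the stated power scenario: per-allele effect 0.3 SD at MAF ~ 0.3, n ~ 1200
  target <- d$geno$snps$id[which.min(abs(d$geno$snps$maf - 0.3))]
  p <- simulate_scan_pvalues(d, n_reps = 40, beta_snp = 0.3, seed = 61,
                             snp = target)
  expect_gt(mean(p <= 0.001), 0.8)
})

test_that("interaction scan: null modifier handling, power, skip guard", {
  d <- fixture_dataset()
  isc <- interaction_scan("fasting_glucose", d$geno, d$phen, d$phi,
                          modifier = "age45", pcs = d$pcs)
  expect_false(attr(isc, "skipped"))
  expect_true(all(isc$p > 0 & isc$p <= 1, na.rm = TRUE))
  expect_equal(attr(isc, "global_alpha"), 0.2)

  # degenerate stratum: everyone under 45 -> skip, no crash
  ph2 <- d$phen
  ph2$age <- pmin(ph2$age, 40)
  expect_message(
    sk <- interaction_scan("fasting_glucose", d$geno, ph2, d$phi,
                           modifier = "age45", pcs = d$pcs),
    "skipped")
  expect_true(attr(sk, "skipped"))
  expect_equal(nrow(sk), 0L)

  # power: effect confined to the older stratum is detected at the screen
  dc <- fixture_dataset("power", n_pedigrees = 38, n_snps = 24, seed = 51,
                        ld_block_size = 8)
  target <- dc$geno$snps$id[which.min(abs(dc$geno$snps$maf - 0.3))]
  p <- simulate_scan_pvalues(dc, n_reps = 40, beta_snp = 0,
                             interaction_beta = 0.4, seed = 62, snp = target)
  thr <- 0.2 / attr(interaction_scan("fasting_glucose", dc$geno, dc$phen,
                                     dc$phi, pcs = dc$pcs),
                    "m_eff")$m_eff
  expect_gt(mean(p <= thr), 0.5)
})

test_that("subgroup fits: full-sample degeneracy and partition accounting", {
  d <- fixture_dataset()
  s <- d$geno$snps$id[3]
  scan <- mga_scan("fasting_glucose", d$geno, d$phen, d$phi, pcs = d$pcs,
                   snps = s)
  full <- subgroup_fit("fasting_glucose", s, d$geno, d$phen, d$phi,
                       modifier = NULL, pcs = d$pcs)
  expect_equal(full$beta, scan$beta[1], tolerance = 1e-10)
  expect_equal(full$p, scan$p[1], tolerance = 1e-10)
  expect_equal(full$n, scan$n[1])

  lo <- subgroup_fit("fasting_glucose", s, d$geno, d$phen, d$phi,
                     modifier = "age45", level = 0, pcs = d$pcs)
  hi <- subgroup_fit("fasting_glucose", s, d$geno, d$phen, d$phi,
                     modifier = "age45", level = 1, pcs = d$pcs)
  expect_equal(lo$n + hi$n, full$n)
})
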