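test_that("pedigree templates: degenerate, sized, and deterministic", {
  # degenerate template: founder couples only
  cfg0 <- sim_config(n_pedigrees = 3, n_children = 0, seed = 5)
  ped0 <- simulate_pedigrees(cfg0)
  expect_equal(nrow(ped0), 6L)
  expect_true(all(is.na(ped0$father) & is.na(ped0$mother)))

  expect_error(sim_config(n_children = -1), "template")

  # default template: 42 families within 5% of 1,383 individuals
  cfg <- sim_config(seed = 7)
  ped <- simulate_pedigrees(cfg)
  expect_lt(abs(nrow(ped) - 1383) / 1383, 0.05)

  # determinism under a fixed seed, through all three generators
  cfg2 <- sim_config(n_pedigrees = 4, n_snps = 15, seed = 11)
  run <- function() {
    p <- simulate_pedigrees(cfg2)
    g <- simulate_genotypes(p, cfg2)
    t <- simulate_traits(p, g, config = cfg2)
    list(p = p, g = g$dosage, t = t)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$p, r2$p)
  expect_identical(r1$g, r2$g)
  expect_identical(r1$t, r2$t)
})

test_that("founder haplotype pool realizes the block-LD structure", {
  mafs <- rep(0.3, 12)
  block <- rep(1:2, each = 6)
  set.seed(21)
  # independent blocks, rho = 0: near-zero correlation everywhere
  H0 <- simulate_founder_pool(10000, mafs, block, rho = 0)
  C0 <- abs(stats::cor(H0))
  expect_lt(mean(C0[upper.tri(C0)]), 0.05)
  # strong LD: within-block correlation well above cross-block
  H1 <- simulate_founder_pool(10000, mafs, block, rho = 0.85)
  C1 <- stats::cor(H1)
  within <- C1[upper.tri(C1)][outer(block, block, "==")[upper.tri(C1)]]
  across <- C1[upper.tri(C1)][outer(block, block, "!=")[upper.tri(C1)]]
  expect_gt(mean(within), 0.3)
  expect_lt(mean(abs(across)), 0.05)
  # monomorphic request is rejected
  expect_error(simulate_founder_pool(10, c(0, 0.2), c(1, 1), 0), "monomorphic")
})

test_that("gene-dropped genotypes are Mendelian and polymorphic", {
  d <- fixture_dataset()
  expect_equal(nrow(check_mendelian(d$geno, d$ped)), 0L)
  expect_true(all(d$geno$snps$maf > 0))
  expect_true(all(d$geno$dosage %in% 0:2))
})

test_that("HOMA derivations follow the printed formulas", {
  expect_equal(derive_homa_ir(5.0, 9.0), 2.0)
  expect_equal(derive_homa_ir(22.5, 1.0), 1.0)
  expect_equal(derive_homa_ir(c(4, 6, 9), 0), c(0, 0, 0))
  expect_error(derive_homa_ir(0, 5), "positive")
  expect_error(derive_homa_ir(5, -1), "non-negative")

  expect_equal(derive_homa_beta(5.5, 10.0), 100.0)
  expect_equal(derive_homa_beta(4.5, 1.0), 20.0)
  expect_warning(out <- derive_homa_beta(c(3.5, 5.5), c(2, 10)), "3.5")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 100.0)
  expect_error(derive_homa_beta(3.4, 2, strict = TRUE), "undefined")
})

test_that("T2D classification respects inclusive thresholds and missingness", {
  expect_false(classify_t2d(6.9, 11.0, FALSE))
  expect_true(classify_t2d(7.0, NA, FALSE))   # fasting boundary inclusive
  expect_true(classify_t2d(5.0, 11.1, FALSE)) # 2-h boundary inclusive
  expect_true(classify_t2d(5.0, 5.0, TRUE))   # medication alone suffices
  expect_true(is.na(classify_t2d(NA, NA, NA)))
  expect_false(classify_t2d(6.0, NA, NA))     # negative on available data
})

test_that("phenotype table honors its structural invariants", {
  d <- fixture_dataset()
  ph <- d$phen
  # incident status undefined for baseline-prevalent individuals
  expect_true(all(is.na(ph$incident_t2d[ph$prevalent_t2d == 1L])))
  # ever = prevalent or incident
  expect_equal(ph$ever_t2d,
               as.integer(ph$prevalent_t2d == 1L |
                            (!is.na(ph$incident_t2d) & ph$incident_t2d == 1L)))
  # HOMA columns reproducible from the glucose/insulin columns
  expect_equal(ph$homa_ir,
               derive_homa_ir(ph$fasting_glucose, ph$fasting_insulin))
  expect_equal(ph$homa_beta,
               suppressWarnings(
                 derive_homa_beta(ph$fasting_glucose, ph$fasting_insulin)))
})

test_that("baseline prevalence is calibrated (pooled n ~ 10,000)", {
  # dense kinship at n = 10,000 is infeasible; pool 8 independent cohorts
  affected <- 0L; total <- 0L
  for (k in 1:8) {
    cfg <- sim_config(n_pedigrees = 39, n_snps = 10, seed = 100 + k)
    ped <- simulate_pedigrees(cfg)
    ph <- simulate_traits(ped, config = cfg)
    affected <- affected + sum(ph$prevalent_t2d)
    total <- total + nrow(ph)
  }
  expect_gt(total, 9500)
  expect_lt(abs(affected / total - 0.15), 0.01)
})

test_that("sib correlation matches 2*phi*h2; h2 = 0 gives independence", {
  h2 <- 0.6
  cors <- c(); cors0 <- c()
  for (k in 1:5) {
    cfg <- sim_config(n_pedigrees = 400, n_children = 2, n_grandchildren = 0,
                      n_snps = 5, seed = 200 + k,
                      h2 = c(liability_prev = 0.5, liability_inc = 0.5,
                             fasting_glucose = h2, fasting_insulin = 0,
                             glucose_2h = 0.3, insulin_2h = 0.3),
                      covariate_effects = c(age = 0, age2 = 0, female = 0,
                                            age_female = 0, age2_female = 0),
                      mask_prevalent = FALSE)
    ped <- simulate_pedigrees(cfg)
    ph <- simulate_traits(ped, config = cfg)
    kid <- !is.na(ped$father)
    sib <- matrix(log(ph$fasting_glucose[kid]), ncol = 2, byrow = TRUE)
    sib0 <- matrix(log(ph$fasting_insulin[kid]), ncol = 2, byrow = TRUE)
    cors <- c(cors, stats::cor(sib[, 1], sib[, 2]))
    cors0 <- c(cors0, stats::cor(sib0[, 1], sib0[, 2]))
  }
  expect_lt(abs(mean(cors) - 2 * 0.25 * h2), 0.05) # closed form: 0.30
  expect_lt(abs(mean(cors0)), 0.05)                # h2 = 0 limit
})

test_that("cohort accounting works on tables and on marginal counts", {
  d <- fixture_dataset()
  acc <- t2d_accounting(d$phen)
  expect_equal(acc$n_ever, acc$n_prevalent + acc$n_incident)
  expect_equal(acc$pct_ever, 100 * acc$n_ever / acc$n_total)
  expect_true(acc$n_followed <= acc$n_total - acc$n_prevalent)
})
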