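#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. The defaults
#' emulate the statistical structure the downstream analysis assumes: 42
#' extended three-generation pedigrees totalling about 1,400 individuals, 118
#' SNPs in one ~100 kb locus with strong block LD, a minor-allele-frequency
#' spectrum with bins <1% / 1-5% / >5% in proportions 10:13:95, ages with
#' mean 39.17 y (older founders, younger grandchildren), ~59.4% females,
#' polygenic heritabilities per trait, and binary prevalent/incident
#' type-2-diabetes traits generated by liability thresholding at a 15%
#' baseline prevalence and 16.3% incidence among the followed at-risk subset.
#'
#' @param n_pedigrees number of families.
#' @param n_children founder couple's number of children (0 gives families of
#'   two unrelated founders).
#' @param n_grandchildren children per child-spouse couple.
#' @param n_snps number of SNPs at the locus.
#' @param ld_block_size SNPs per LD block (last block may be shorter).
#' @param ld_rho within-block latent (copula) correlation, in [0, 1).
#' @param maf_bins data frame with columns `lower`, `upper`, `n`: MAFs are
#'   drawn uniformly within each bin, bin counts rescaled to `n_snps`.
#' @param h2 named vector of polygenic heritabilities: entries
#'   `liability_prev`, `liability_inc`, `fasting_glucose`, `fasting_insulin`,
#'   `glucose_2h`, `insulin_2h` (HOMA indices are derived, not simulated).
#' @param qtn_effects optional named list `trait -> named vector snp -> beta`
#'   of per-allele effects in latent-trait SD units (default none: a null
#'   locus).
#' @param covariate_effects named vector of coefficients for the standardized
#'   covariate design (age, age^2, female, age x female, age^2 x female)
#'   shared by all latent traits.
#' @param prevalence_baseline baseline T2D prevalence.
#' @param prevalence_incident incidence among followed, baseline-unaffected
#'   individuals.
#' @param prop_followup fraction of baseline-unaffected individuals with
#'   complete follow-up (913/1175 in the emulated cohort).
#' @param age_gen_means mean age per generation (founders, children,
#'   grandchildren); defaults solve to an overall mean of 39.17 y.
#' @param age_sd within-generation age standard deviation (gamma noise,
#'   right-skewed).
#' @param prop_female probability that a non-spouse individual is female.
#' @param mask_prevalent if TRUE (default) continuous traits are set missing
#'   for baseline-prevalent individuals, mirroring cohorts that report
#'   glucose/insulin only for the initially unaffected.
#' @param seed integer seed; fixed seed implies bit-identical output.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_pedigrees = 42,
                       n_children = 5,
                       n_grandchildren = 4,
                       n_snps = 118,
                       ld_block_size = 10,
                       ld_rho = 0.85,
                       maf_bins = data.frame(
                         lower = c(0.007, 0.01, 0.05),
                         upper = c(0.01, 0.05, 0.4989),
                         n = c(10, 13, 95)),
                       h2 = c(liability_prev = 0.65, liability_inc = 0.66,
                              fasting_glucose = 0.42, fasting_insulin = 0.42,
                              glucose_2h = 0.37, insulin_2h = 0.32),
                       qtn_effects = NULL,
                       covariate_effects = c(age = 0.30, age2 = 0.10,
                                             female = 0.10, age_female = 0.05,
                                             age2_female = 0.02),
                       prevalence_baseline = 0.15,
                       prevalence_incident = 0.163,
                       prop_followup = 913 / 1175,
                       age_gen_means = c(75, 52, 29.17),
                       age_sd = 6,
                       prop_female = 0.594,
                       mask_prevalent = TRUE,
                       seed = NULL) {
  cfg <- list(n_pedigrees = n_pedigrees, n_children = n_children,
              n_grandchildren = n_grandchildren, n_snps = n_snps,
              ld_block_size = ld_block_size, ld_rho = ld_rho,
              maf_bins = maf_bins, h2 = h2, qtn_effects = qtn_effects,
              covariate_effects = covariate_effects,
              prevalence_baseline = prevalence_baseline,
              prevalence_incident = prevalence_incident,
              prop_followup = prop_followup,
              age_gen_means = age_gen_means, age_sd = age_sd,
              prop_female = prop_female, mask_prevalent = mask_prevalent,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pedigrees < 1) stop("n_pedigrees must be >= 1")
    if (n_children < 0 || n_grandchildren < 0) {
      stop("invalid pedigree template: negative offspring counts")
    }
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
    if (any(maf_bins$lower <= 0) || any(maf_bins$upper > 0.5)) {
      stop("MAF bins must lie in (0, 0.5]")
    }
    if (any(h2 < 0 | h2 >= 1)) stop("heritabilities must lie in [0, 1)")
    fr <- c(prevalence_baseline, prevalence_incident, prop_followup)
    if (any(fr < 0 | fr >= 1)) stop("prevalence/follow-up fractions must lie in [0, 1)")
    if (!is.null(seed) && abs(seed) >= 2^31 - 16) stop("seed out of 32-bit range")
  })
  structure(cfg, class = "sim_config")
}

#' Simulate extended pedigrees
#'
#' Builds `n_pedigrees` families from a three-generation outbred template:
#' one founder couple, `n_children` children each married to an unrelated
#' spouse (also a founder), and `n_grandchildren` children per couple. With
#' the default template each family has `2 + 2*n_children +
#' n_children*n_grandchildren` members (32), so 42 families total 1,344
#' individuals. Child and grandchild sexes are Bernoulli(`prop_female`);
#' spouse sexes are forced opposite.
#'
#' @param config a [sim_config()].
#' @return A [pedigree()].
#' @export
simulate_pedigrees <- function(config) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  rows <- vector("list", config$n_pedigrees)
  for (f in seq_len(config$n_pedigrees)) {
    famid <- sprintf("F%02d", f)
    k <- 0L
    nid <- function() {
      k <<- k + 1L
      sprintf("%s_I%03d", famid, k)
    }
    dad0 <- nid(); mom0 <- nid()
    fam <- data.frame(fam = famid, id = c(dad0, mom0),
                      father = NA_character_, mother = NA_character_,
                      sex = c(1L, 2L), stringsAsFactors = FALSE)
    if (config$n_children > 0) {
      for (ch in seq_len(config$n_children)) {
        child_sex <- if (stats::runif(1) < config$prop_female) 2L else 1L
        child <- nid(); spouse <- nid()
        fam <- rbind(fam, data.frame(
          fam = famid, id = c(child, spouse),
          father = c(dad0, NA_character_), mother = c(mom0, NA_character_),
          sex = c(child_sex, 3L - child_sex), stringsAsFactors = FALSE))
        if (config$n_grandchildren > 0) {
          gk_sex <- ifelse(stats::runif(config$n_grandchildren) < config$prop_female, 2L, 1L)
          gk <- replicate(config$n_grandchildren, nid())
          fam <- rbind(fam, data.frame(
            fam = famid, id = gk,
            father = if (child_sex == 1L) child else spouse,
            mother = if (child_sex == 1L) spouse else child,
            sex = gk_sex, stringsAsFactors = FALSE))
        }
      }
    }
    rows[[f]] <- fam
  }
  validate_pedigree(do.call(rbind, rows))
}

#' Draw a SNP metadata table from the configured MAF spectrum
#'
#' Bin counts are rescaled to `n_snps` by largest remainder; MAFs are uniform
#' within bins; positions are evenly spaced 1-based coordinates across a
#' ~100 kb window on chromosome 8; two mid-locus SNPs are tagged as coding.
#'
#' @param config a [sim_config()].
#' @return Data frame with columns id, chrom, pos, maf, block, coding.
#' @keywords internal
draw_snp_panel <- function(config) {
  bins <- config$maf_bins
  m <- config$n_snps
  raw <- bins$n / sum(bins$n) * m
  cnt <- floor(raw)
  rem <- m - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  mafs <- unlist(lapply(seq_len(nrow(bins)), function(b) {
    stats::runif(cnt[b], bins$lower[b], bins$upper[b])
  }))
  mafs <- sample(mafs) # interleave rarity across the locus
  blk <- rep(seq_len(ceiling(m / config$ld_block_size)),
             each = config$ld_block_size)[seq_len(m)]
  coding <- rep(FALSE, m)
  coding[unique(pmax(1L, round(m * c(0.45, 0.55))))] <- TRUE
  data.frame(
    id = sprintf("snp%03d", seq_len(m)),
    chrom = "8",
    pos = 117910000L + (seq_len(m) - 1L) * as.integer(floor(1e5 / max(m, 1))),
    maf = mafs, block = blk, coding = coding,
    stringsAsFactors = FALSE)
}

#' Simulate a founder haplotype pool with block LD
#'
#' Gaussian-copula haplotypes: a latent normal vector with block-exchangeable
#' correlation `rho` is thresholded at the per-SNP MAF quantile, giving
#' binary minor-allele indicators whose within-block correlation rises with
#' `rho` while cross-block correlation is ~0.
#'
#' @param n_hap number of haplotypes.
#' @param mafs per-SNP minor allele frequencies in (0, 0.5].
#' @param block integer block id per SNP.
#' @param rho latent within-block correlation in [0, 1).
#' @return `n_hap` x `m` 0/1 matrix.
#' @export
simulate_founder_pool <- function(n_hap, mafs, block, rho) {
  if (any(mafs <= 0)) stop("monomorphic SNP requested: MAF must be > 0")
  m <- length(mafs)
  stopifnot(length(block) == m, rho >= 0, rho < 1)
  u <- matrix(stats::rnorm(n_hap * max(block)), n_hap, max(block))
  eps <- matrix(stats::rnorm(n_hap * m), n_hap, m)
  z <- sqrt(rho) * u[, block, drop = FALSE] + sqrt(1 - rho) * eps
  H <- sweep(z, 2, stats::qnorm(mafs), "<") * 1L
  storage.mode(H) <- "integer"
  H
}

#' Simulate genotypes on a pedigree by gene dropping
#'
#' Founders receive two haplotypes from a block-LD Gaussian-copula pool
#' ([simulate_founder_pool()]); every non-founder inherits one whole
#' haplotype from each parent (no recombination within the ~100 kb locus),
#' which preserves both LD and Mendelian transmission. SNPs that come out
#' monomorphic in the realized sample are re-dropped from fresh founder
#' draws, since all downstream analysis requires MAF > 0.
#'
#' @param pedigree a [pedigree()].
#' @param config a [sim_config()].
#' @return A [genotype_matrix()] whose `snps` metadata carries the block id
#'   and coding flags.
#' @export
simulate_genotypes <- function(pedigree, config) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  meta <- draw_snp_panel(config)
  n <- nrow(pedigree)
  m <- nrow(meta)
  fa <- match(pedigree$father, pedigree$id)
  mo <- match(pedigree$mother, pedigree$id)
  ord <- .pedigree_order(pedigree)
  fdr <- which(is.na(fa))
  drop_cols <- function(cols, H1, H2) {
    pool <- simulate_founder_pool(2L * length(fdr), meta$maf[cols],
                                  match(meta$block[cols], unique(meta$block[cols])),
                                  config$ld_rho)
    H1[fdr, cols] <- pool[seq_along(fdr), , drop = FALSE]
    H2[fdr, cols] <- pool[length(fdr) + seq_along(fdr), , drop = FALSE]
    for (i in ord) {
      if (is.na(fa[i])) next
      H1[i, cols] <- if (stats::runif(1) < 0.5) H1[fa[i], cols] else H2[fa[i], cols]
      H2[i, cols] <- if (stats::runif(1) < 0.5) H1[mo[i], cols] else H2[mo[i], cols]
    }
    list(H1 = H1, H2 = H2)
  }
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  hh <- drop_cols(seq_len(m), H1, H2)
  H1 <- hh$H1; H2 <- hh$H2
  for (try in 1:50) {
    dos <- H1 + H2
    mono <- which(colSums(dos) == 0L | colSums(dos) == 2L * n)
    if (!length(mono)) break
    hh <- drop_cols(mono, H1, H2)
    H1 <- hh$H1; H2 <- hh$H2
  }
  dos <- H1 + H2
  storage.mode(dos) <- "double"
  rownames(dos) <- pedigree$id
  colnames(dos) <- meta$id
  genotype_matrix(dos, snps = meta[, c("id", "chrom", "pos", "block", "coding")])
}

#' Unit-variance polygenic draws on a pedigree
#'
#' Draws vectors g ~ MVN(0, 2*Phi) family block by family block (families
#' are mutually unrelated, so the Cholesky factors are per-family). Used both
#' by [simulate_traits()] and directly in calibration simulations.
#'
#' @param pedigree a [pedigree()].
#' @param phi optional precomputed [pedigree_kinship()] matrix.
#' @param n_traits number of independent draws (columns).
#' @return n x `n_traits` matrix with individual ids as rownames.
#' @export
simulate_polygenic <- function(pedigree, phi = NULL, n_traits = 1) {
  if (is.null(phi)) phi <- pedigree_kinship(pedigree)
  chol_blocks <- polygenic_chol(pedigree, phi)
  g <- matrix(0, nrow(pedigree), n_traits,
              dimnames = list(pedigree$id, NULL))
  for (b in chol_blocks) {
    g[b$idx, ] <- crossprod(b$L, matrix(stats::rnorm(length(b$idx) * n_traits),
                                        length(b$idx), n_traits))
  }
  g
}

# Per-family upper Cholesky factors of 2*Phi (cacheable).
polygenic_chol <- function(pedigree, phi) {
  lapply(split(seq_len(nrow(pedigree)), pedigree$fam), function(idx) {
    list(idx = idx, L = chol(2 * unclass(phi)[idx, idx, drop = FALSE]))
  })
}

#' Simulate T2D-related phenotypes on a pedigree
#'
#' Each latent trait follows y = X beta + sum_j beta_j x_j + g + e with
#' polygenic values g of covariance 2*Phi*h2 and independent environmental
#' noise, so that quantitative traits have the configured variance
#' decomposition in expectation. Continuous traits are mapped monotonically
#' to natural scales (lognormal glucose/insulin around realistic means);
#' HOMA indices are then *derived* from the glucose/insulin columns via
#' [derive_homa_ir()] / [derive_homa_beta()]. Prevalent T2D arises by
#' thresholding a liability at the quantile matching
#' `prevalence_baseline`; incident T2D applies a second liability (sharing
#' the polygenic component) thresholded empirically within the followed
#' at-risk subset so that the configured incidence is realized.
#'
#' @param pedigree a [pedigree()].
#' @param genotypes a [genotype_matrix()] (used when `qtn_effects` are set).
#' @param kinship optional [pedigree_kinship()] matrix.
#' @param config a [sim_config()].
#' @return A data frame of class `"phenotype_table"` with columns fam, id,
#'   age, sex, prevalent_t2d, incident_t2d, ever_t2d, medication_flag and the
#'   six continuous traits plus the two derived HOMA indices.
#' @export
simulate_traits <- function(pedigree, genotypes = NULL, kinship = NULL,
                            config = sim_config()) {
  config <- validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed + 2L)
  if (is.null(kinship)) kinship <- pedigree_kinship(pedigree)
  n <- nrow(pedigree)
  depth <- pedigree_depth(pedigree)
  gen_mean <- config$age_gen_means[pmin(depth + 1L, length(config$age_gen_means))]
  shape <- (gen_mean / config$age_sd)^2
  age <- stats::rgamma(n, shape = shape, rate = shape / gen_mean)
  female <- as.numeric(pedigree$sex == 2L)
  age_s <- (age - 39.17) / 15
  Xc <- cbind(age = age_s, age2 = age_s^2, female = female,
              age_female = age_s * female, age2_female = age_s^2 * female)
  xb <- drop(Xc %*% config$covariate_effects[colnames(Xc)])

  chol_blocks <- polygenic_chol(pedigree, kinship)
  draw_g <- function() {
    g <- numeric(n)
    for (b in chol_blocks) {
      g[b$idx] <- crossprod(b$L, stats::rnorm(length(b$idx)))
    }
    g
  }
  qtn_part <- function(trait) {
    eff <- config$qtn_effects[[trait]]
    if (is.null(eff) || is.null(genotypes)) {
      return(list(value = 0, var = 0))
    }
    G <- genotypes$dosage[pedigree$id, names(eff), drop = FALSE]
    p <- colMeans(G) / 2
    list(value = drop(G %*% eff), var = sum(eff^2 * 2 * p * (1 - p)))
  }
  latent <- function(trait) {
    h2 <- unname(config$h2[trait])
    q <- qtn_part(trait)
    if (h2 + q$var >= 1) {
      stop("variance fractions sum to >= 1 for trait ", trait)
    }
    e2 <- 1 - h2 - q$var
    list(y = xb + q$value + sqrt(h2) * draw_g() + stats::rnorm(n, sd = sqrt(e2)),
         g = NULL)
  }
  to_lognormal <- function(y, mean_nat, sdlog) {
    z <- (y - mean(y)) / stats::sd(y)
    exp(log(mean_nat) - sdlog^2 / 2 + sdlog * z)
  }

  # prevalence liability; incident liability shares the polygenic component
  h2p <- unname(config$h2["liability_prev"])
  h2i <- unname(config$h2["liability_inc"])
  qp <- qtn_part("liability_prev")
  if (h2p + qp$var >= 1 || h2i >= 1) stop("liability variance fractions sum to >= 1")
  g_liab <- draw_g()
  liab_prev <- xb + qp$value + sqrt(h2p) * g_liab +
    stats::rnorm(n, sd = sqrt(1 - h2p - qp$var))
  thr <- stats::qnorm(1 - config$prevalence_baseline,
                      mean = mean(xb), sd = sqrt(stats::var(xb) + 1))
  prevalent <- liab_prev > thr

  liab_inc <- xb + sqrt(h2i) * g_liab + stats::rnorm(n, sd = sqrt(1 - h2i))
  at_risk <- !prevalent
  followed <- at_risk & (stats::runif(n) < config$prop_followup)
  incident <- rep(NA, n)
  if (any(followed)) {
    cut <- stats::quantile(liab_inc[followed], 1 - config$prevalence_incident,
                           names = FALSE, type = 7)
    incident[followed] <- liab_inc[followed] > cut
  }
  ever <- prevalent | (!is.na(incident) & incident)
  medication <- prevalent & (stats::runif(n) < 0.5)

  fg <- to_lognormal(latent("fasting_glucose")$y, 4.82, 0.15)
  fi <- to_lognormal(latent("fasting_insulin")$y, 14.11, 0.60)
  g2 <- to_lognormal(latent("glucose_2h")$y, 5.61, 0.25)
  i2 <- to_lognormal(latent("insulin_2h")$y, 76.86, 0.80)
  if (config$mask_prevalent) {
    fg[prevalent] <- NA; fi[prevalent] <- NA
    g2[prevalent] <- NA; i2[prevalent] <- NA
  }
  out <- data.frame(
    fam = pedigree$fam, id = pedigree$id,
    age = age, sex = pedigree$sex,
    prevalent_t2d = as.integer(prevalent),
    incident_t2d = ifelse(is.na(incident), NA_integer_, as.integer(incident)),
    ever_t2d = as.integer(ever),
    medication_flag = as.integer(medication),
    fasting_glucose = fg, fasting_insulin = fi,
    glucose_2h = g2, insulin_2h = i2,
    stringsAsFactors = FALSE)
  out$homa_ir <- derive_homa_ir(out$fasting_glucose, out$fasting_insulin)
  out$homa_beta <- suppressWarnings(
    derive_homa_beta(out$fasting_glucose, out$fasting_insulin))
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' HOMA insulin-resistance index
#'
#' HOMA-IR = fasting glucose (mmol/L) x fasting insulin (uU/mL) / 22.5.
#'
#' @param fasting_glucose glucose in mmol/L (> 0).
#' @param fasting_insulin insulin in uU/mL (>= 0).
#' @return Numeric vector; NA inputs propagate.
#' @export
derive_homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0, na.rm = TRUE)) {
    stop("fasting glucose must be positive (mmol/L)")
  }
  if (any(fasting_insulin < 0, na.rm = TRUE)) {
    stop("fasting insulin must be non-negative (uU/mL)")
  }
  fasting_glucose * fasting_insulin / 22.5
}

#' HOMA beta-cell-function index
#'
#' HOMA-beta = 20 x fasting insulin (uU/mL) / (fasting glucose (mmol/L) - 3.5).
#' The formula is singular at glucose = 3.5 mmol/L; values at or below the
#' singularity are flagged missing with a warning (or rejected when
#' `strict = TRUE`).
#'
#' @inheritParams derive_homa_ir
#' @param strict error (rather than return NA) on glucose <= 3.5.
#' @return Numeric vector; NA for glucose <= 3.5 unless `strict`.
#' @export
derive_homa_beta <- function(fasting_glucose, fasting_insulin, strict = FALSE) {
  bad <- !is.na(fasting_glucose) & fasting_glucose <= 3.5
  if (any(bad)) {
    if (strict) stop("fasting glucose <= 3.5 mmol/L: HOMA-beta undefined")
    warning(sum(bad), " value(s) with fasting glucose <= 3.5 mmol/L set to NA")
  }
  out <- 20 * fasting_insulin / (fasting_glucose - 3.5)
  out[bad] <- NA_real_
  out
}

#' Classify T2D status from glucose measurements and medication use
#'
#' Positive iff fasting glucose >= 7.0 mmol/L (126 mg/dL), 2-hour
#' post-challenge glucose >= 11.1 mmol/L (200 mg/dL), or antidiabetic
#' medication use; thresholds inclusive. With every input missing the status
#' is missing, not negative.
#'
#' @param fasting_glucose,glucose_2h mmol/L, NA allowed.
#' @param on_medication logical, NA allowed.
#' @return Logical vector (TRUE/FALSE/NA).
#' @export
classify_t2d <- function(fasting_glucose, glucose_2h = NA, on_medication = NA) {
  k <- max(length(fasting_glucose), length(glucose_2h), length(on_medication))
  fg <- rep_len(fasting_glucose, k)
  g2 <- rep_len(glucose_2h, k)
  med <- rep_len(as.logical(on_medication), k)
  crit <- cbind(fg >= 7.0, g2 >= 11.1, med)
  pos <- apply(crit, 1, function(r) any(r, na.rm = TRUE))
  all_na <- apply(crit, 1, function(r) all(is.na(r)))
  pos[all_na] <- NA
  pos
}

#' Cohort T2D accounting
#'
#' Tabulates prevalent, incident and ever-T2D counts and percentages either
#' from a simulated [simulate_traits()] table or from supplied marginal
#' counts (total n, prevalent cases, followed at-risk individuals, incident
#' cases). Ever-T2D = prevalent + incident-among-followed; percentages are
#' prevalent/total, incident/followed, ever/total.
#'
#' @param phenotypes optional `"phenotype_table"`.
#' @param n_total,n_prevalent,n_followed,n_incident marginal counts, used
#'   when `phenotypes` is NULL.
#' @return List with the four counts and `pct_prevalent`, `pct_incident`,
#'   `pct_ever`, `n_ever`.
#' @export
t2d_accounting <- function(phenotypes = NULL, n_total = NULL,
                           n_prevalent = NULL, n_followed = NULL,
                           n_incident = NULL) {
  if (!is.null(phenotypes)) {
    n_total <- nrow(phenotypes)
    n_prevalent <- sum(phenotypes$prevalent_t2d == 1L, na.rm = TRUE)
    n_followed <- sum(!is.na(phenotypes$incident_t2d))
    n_incident <- sum(phenotypes$incident_t2d == 1L, na.rm = TRUE)
  }
  n_ever <- n_prevalent + n_incident
  list(n_total = n_total, n_prevalent = n_prevalent,
       n_followed = n_followed, n_incident = n_incident, n_ever = n_ever,
       pct_prevalent = 100 * n_prevalent / n_total,
       pct_incident = 100 * n_incident / n_followed,
       pct_ever = 100 * n_ever / n_total)
}

#' MAF bin table
#'
#' Counts and percentages of SNPs per minor-allele-frequency bin
#' (default bins: <1%, 1-5%, >5%).
#'
#' @param mafs numeric vector of MAFs.
#' @param breaks bin edges (left-closed, right-open except the last bin).
#' @return Data frame with columns bin, n, pct.
#' @export
maf_bin_table <- function(mafs, breaks = c(0, 0.01, 0.05, 0.5)) {
  cuts <- cut(mafs, breaks = breaks, right = FALSE,
              include.lowest = TRUE,
              labels = c("<1%", "1-5%", ">5%"))
  # right edge of the last bin is closed (MAF = 0.5 counts as >5%)
  cuts[mafs == breaks[length(breaks)]] <- ">5%"
  tab <- table(cuts)
  data.frame(bin = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / length(mafs),
             stringsAsFactors = FALSE)
}

#' Read / write phenotype tables as CSV
#'
#' Headered comma-separated file with `NA` as the missing-value token.
#'
#' @param phenotypes a phenotype data frame.
#' @param path file path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  out <- utils::read.csv(path, na.strings = "NA", stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}
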