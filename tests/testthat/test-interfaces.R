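test_that("pedigree files round-trip and parse order-independently", {
  d <- fixture_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(d$ped, path)
  ped2 <- read_pedigree(path)
  expect_equal(as.data.frame(ped2), as.data.frame(d$ped))

  # child listed before its parents still parses
  shuffled <- as.data.frame(d$ped)[rev(seq_len(nrow(d$ped))), ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(validate_pedigree(shuffled), path2)
  expect_s3_class(read_pedigree(path2), "pedigree")

  # structural errors are caught with the offender named
  bad <- as.data.frame(d$ped)
  bad$id[2] <- bad$id[1]
  expect_error(validate_pedigree(bad), "duplicate")
  cyc <- data.frame(fam = "f", id = c("a", "b", "c"),
                    father = c("c", NA, "a"), mother = c("b", NA, "b"),
                    sex = c(1, 2, 1))
  expect_error(validate_pedigree(cyc), "cyclic")
})

test_that("VCF and dosage TSV agree; GT falls back when DS is absent", {
  skip_if_not_installed("VariantAnnotation")
  d <- fixture_dataset()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_vcf(d$geno, vcf)
  write_genotypes_tsv(d$geno, tsv)
  g_vcf <- suppressWarnings(read_genotypes(vcf))
  g_tsv <- read_genotypes(tsv)
  expect_equal(g_vcf$dosage[rownames(g_tsv$dosage), colnames(g_tsv$dosage)],
               g_tsv$dosage)
  expect_equal(g_vcf$snps$pos, d$geno$snps$pos)

  # GT-only VCF: 0/1 -> dosage 1
  gt_vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "i1", "i2", "i3", sep = "\t"),
    paste("8", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1/1", "0/0", sep = "\t")), gt_vcf)
  g_gt <- suppressWarnings(read_genotypes(gt_vcf))
  expect_equal(unname(g_gt$dosage[, "rs1"]), c(1, 2, 0))

  # sample reconciliation lists offenders
  expect_error(read_genotypes(tsv, samples = c(d$ped$id[-1], "ghost")),
               "ghost")
})

test_that("phenotype CSV round-trips with missing values", {
  d <- fixture_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(d$phen, path)
  ph2 <- read_phenotypes(path)
  expect_equal(as.data.frame(ph2), as.data.frame(d$phen), tolerance = 1e-12)
})

test_that("pipeline runs end-to-end, deterministically, with provenance", {
  cfg <- sim_config(n_pedigrees = 5, n_snps = 16, ld_block_size = 8, seed = 4)
  ped <- simulate_pedigrees(cfg)
  geno <- simulate_genotypes(ped, cfg)
  phen <- simulate_traits(ped, geno, config = cfg)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  traits <- c("fasting_glucose", "ever_t2d")
  snapshot <- list(phen = as.data.frame(phen), dosage = geno$dosage)
  r1 <- suppressMessages(run_pipeline(
    run_config(ped, geno, phen, traits = traits, outdir = out1)))
  r2 <- suppressMessages(run_pipeline(
    run_config(ped, geno, phen, traits = traits, outdir = out2)))
  files <- sort(list.files(out1))
  expect_true(all(c("burden.tsv", "ps.tsv", "run_config.json",
                    "mga_fasting_glucose.tsv") %in% files))
  expect_equal(files, sort(list.files(out2)))
  for (f in files) { # byte-identical result tree across two runs
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
  # provenance header on every TSV
  hdr <- readLines(file.path(out1, "burden.tsv"), n = 3)
  expect_match(hdr[1], "^# famvc .* stage=burden")
  expect_match(hdr[2], "config_hash=")
  # stages never mutate inputs
  expect_identical(as.data.frame(phen), snapshot$phen)
  expect_identical(geno$dosage, snapshot$dosage)
})

test_that("a planted QTN is carried from the scan into MSA and BQTN", {
  cfg <- sim_config(
    n_pedigrees = 12, n_snps = 16, ld_block_size = 4, ld_rho = 0.4, seed = 71,
    qtn_effects = list(fasting_glucose = c(snp010 = 0.45),
                       fasting_insulin = c(snp010 = 0.45),
                       glucose_2h = c(snp010 = 0.45)))
  ped <- simulate_pedigrees(cfg)
  geno <- simulate_genotypes(ped, cfg)
  phen <- simulate_traits(ped, geno, config = cfg)
  out <- withr::local_tempdir()
  res <- suppressMessages(run_pipeline(run_config(
    ped, geno, phen,
    traits = c("fasting_glucose", "fasting_insulin", "glucose_2h"),
    outdir = out)))
  expect_true("snp010" %in% res$msa)
  expect_true("snp010" %in% res$bqtn$fasting_glucose$best_snps)
  # model accounting: 2^|MSA| models per trait, logged total
  expect_equal(res$n_bqtn_models, 3 * 2^length(res$msa))
})

test_that("the CLI drives simulate and assoc from files", {
  out <- withr::local_tempdir()
  cfg_path <- file.path(out, "sim.json")
  jsonlite::write_json(list(n_pedigrees = 4, n_snps = 12, ld_block_size = 6),
                       cfg_path, auto_unbox = TRUE)
  suppressMessages(famvc_cli(c("simulate", "--config", cfg_path,
                               "--out", out, "--seed", "3")))
  expect_true(all(file.exists(file.path(
    out, c("pedigree.tsv", "dosages.tsv", "genotypes.vcf", "phenotypes.csv")))))
  res_path <- file.path(out, "scan.tsv")
  suppressMessages(famvc_cli(c(
    "assoc", "--trait", "fasting_glucose",
    "--ped", file.path(out, "pedigree.tsv"),
    "--dosages", file.path(out, "dosages.tsv"),
    "--pheno", file.path(out, "phenotypes.csv"),
    "--out", res_path)))
  scan <- utils::read.delim(res_path)
  expect_true(all(c("snp", "beta", "p", "neglog10p") %in% names(scan)))
  expect_equal(nrow(scan), 12L)
})
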