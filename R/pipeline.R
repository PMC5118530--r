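#' Pipeline run configuration
#'
#' Bundles inputs, trait list, thresholds and policies for [run_pipeline()].
#' Inputs may be in-memory objects ([pedigree()], [genotype_matrix()],
#' phenotype data frame) or file paths (FAM-style TSV, VCF/dosage TSV,
#' phenotype CSV); paths are resolved and validated at run time.
#'
#' @param pedigree,genotypes,phenotypes objects or file paths.
#' @param traits trait columns to analyze; NULL selects the standard eight
#'   T2D-related traits present in the phenotype table.
#' @param global_alpha global type-I error rate of the MGA stage.
#' @param interaction_alpha liberal global rate of the interaction screen.
#' @param ps_threshold cross-trait probability-score significance preset.
#' @param msa_max cap on the PS-selected SNP panel passed to BQTN.
#' @param n_e BQTN effective sample size (`"auto"` = complete-case n).
#' @param seed integer seed recorded in provenance (analyses themselves are
#'   deterministic).
#' @param outdir output directory.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(pedigree, genotypes, phenotypes, traits = NULL,
                       global_alpha = 0.05, interaction_alpha = 0.2,
                       ps_threshold = 4.3010, msa_max = 20, n_e = "auto",
                       seed = 1, outdir = "famvc_out") {
  stopifnot(global_alpha > 0, global_alpha < 1,
            interaction_alpha > 0, interaction_alpha < 1,
            ps_threshold >= 0)
  for (p in list(pedigree, genotypes, phenotypes)) {
    if (is.character(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(list(pedigree = pedigree, genotypes = genotypes,
                 phenotypes = phenotypes, traits = traits,
                 global_alpha = global_alpha,
                 interaction_alpha = interaction_alpha,
                 ps_threshold = ps_threshold, msa_max = msa_max, n_e = n_e,
                 seed = seed, outdir = outdir),
            class = "run_config")
}

# Serializable view of a config (paths kept, objects summarized).
.config_provenance <- function(config) {
  desc <- lapply(config[c("pedigree", "genotypes", "phenotypes")], function(p) {
    if (is.character(p)) p else paste0("<in-memory:", class(p)[1], ">")
  })
  c(desc, config[c("traits", "global_alpha", "interaction_alpha",
                   "ps_threshold", "msa_max", "n_e", "seed")])
}

# Polynomial rolling hash (mod 2^32) of the serialized config, for
# provenance headers; stability matters here, not cryptography.
.config_hash <- function(config) {
  s <- jsonlite::toJSON(.config_provenance(config), auto_unbox = TRUE,
                        null = "null")
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

.provenance_header <- function(config, stage) {
  c(paste0("# famvc ", as.character(utils::packageVersion("famvc")),
           " stage=", stage),
    paste0("# config_hash=", .config_hash(config), " seed=", config$seed),
    paste0("# global_alpha=", config$global_alpha,
           " interaction_alpha=", config$interaction_alpha,
           " ps_threshold=", config$ps_threshold))
}

.write_stage_tsv <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(config, stage), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.standard_traits <- c("ever_t2d", "incident_t2d", "fasting_glucose",
                      "fasting_insulin", "glucose_2h", "insulin_2h",
                      "homa_ir", "homa_beta")

#' Run the full association pipeline
#'
#' Executes the four analysis levels in order on one dataset: (1)
#' measured-genotype association of every SNP with every trait, (2) the
#' cross-trait probability score selecting the most significantly associated
#' (MSA) SNP panel, (3) genotype-by-age and genotype-by-sex interaction
#' screens, (4) exhaustive BQTN model selection over the MSA panel per
#' trait, and (5) the locus burden test on three SNP sets (all, coding,
#' MSA). Every output file carries a provenance header (package version,
#' config hash, seed, thresholds); stages never mutate each other's inputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the per-stage results and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ped <- if (is.character(config$pedigree)) {
    read_pedigree(config$pedigree)
  } else config$pedigree
  geno <- if (is.character(config$genotypes)) {
    read_genotypes(config$genotypes, samples = ped$id)
  } else config$genotypes
  phen <- if (is.character(config$phenotypes)) {
    read_phenotypes(config$phenotypes)
  } else config$phenotypes
  if (!all(ped$id %in% rownames(geno$dosage))) {
    stop("pipeline halted at stage=input: genotype samples do not cover the pedigree")
  }
  traits <- config$traits
  if (is.null(traits)) traits <- intersect(.standard_traits, names(phen))
  if (!length(traits)) stop("pipeline halted at stage=input: no traits to analyze")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.config_provenance(config),
                       file.path(config$outdir, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  phi <- pedigree_kinship(ped)
  pcs <- genotype_pcs(geno)

  # stage 1: measured-genotype association, one scan per trait
  scans <- list()
  for (tr in traits) {
    scans[[tr]] <- tryCatch(
      mga_scan(tr, geno, phen, phi, pcs = pcs,
               global_alpha = config$global_alpha),
      error = function(e) stop("pipeline halted at stage=mga trait=", tr,
                               ": ", conditionMessage(e)))
    .write_stage_tsv(scans[[tr]],
                     file.path(config$outdir, paste0("mga_", tr, ".tsv")),
                     config, paste0("mga:", tr))
  }

  # stage 2: cross-trait probability score -> MSA panel
  pmat <- do.call(cbind, lapply(scans, function(s) s$p))
  rownames(pmat) <- scans[[1]]$snp
  pmat_use <- pmat[stats::complete.cases(pmat), , drop = FALSE]
  ps <- ps_score(pmat_use, threshold = config$ps_threshold)
  .write_stage_tsv(ps, file.path(config$outdir, "ps.tsv"), config, "ps")
  msa <- ps$snp[ps$flagged]
  if (length(msa) > config$msa_max) {
    msa <- ps$snp[order(ps$ps, decreasing = TRUE)][seq_len(config$msa_max)]
  }

  # stage 3: interaction screens
  interactions <- list()
  for (mod in c("age45", "sex")) {
    for (tr in traits) {
      key <- paste(tr, mod, sep = "_")
      interactions[[key]] <- interaction_scan(
        tr, geno, phen, phi, modifier = mod, pcs = pcs,
        global_alpha = config$interaction_alpha)
      .write_stage_tsv(interactions[[key]],
                       file.path(config$outdir,
                                 paste0("interaction_", key, ".tsv")),
                       config, paste0("interaction:", key))
    }
  }

  # stage 4: BQTN on the MSA panel
  bqtn <- list()
  n_models_total <- 0L
  if (length(msa)) {
    n_e <- if (identical(config$n_e, "auto")) NULL else config$n_e
    for (tr in traits) {
      rep_tr <- bqtn_scan(tr, geno, phen, phi, snps = msa, pcs = pcs,
                          n_e = n_e)
      bqtn[[tr]] <- rep_tr
      n_models_total <- n_models_total + nrow(rep_tr$models)
      jsonlite::write_json(
        list(trait = tr, h_r2 = rep_tr$h_r2,
             best_model = rep_tr$best$snps,
             bic_best_vs_null = rep_tr$delta_bic,
             models_in_window = rep_tr$window_n,
             best_snp_p = as.list(rep_tr$best_snp_p),
             n_e = rep_tr$n_e, n = rep_tr$n,
             n_models = nrow(rep_tr$models),
             provenance = list(config_hash = .config_hash(config),
                               seed = config$seed)),
        file.path(config$outdir, paste0("bqtn_", tr, ".json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    message("BQTN stage scored ", n_models_total, " models (",
            length(msa), " MSA SNPs x ", length(traits), " traits)")
  } else {
    message("BQTN stage skipped: no SNP exceeded the PS threshold")
  }

  # stage 5: burden panel on all / coding / MSA SNP sets
  snp_sets <- list(all = geno$snps$id)
  if (any(geno$snps$coding)) snp_sets$coding <- geno$snps$id[geno$snps$coding]
  if (length(msa)) snp_sets$msa <- msa
  burden <- burden_panel(traits, geno, phen, phi, snp_sets, pcs = pcs)
  .write_stage_tsv(burden, file.path(config$outdir, "burden.tsv"),
                   config, "burden")

  invisible(list(outdir = config$outdir, scans = scans, ps = ps, msa = msa,
                 interactions = interactions, bqtn = bqtn,
                 n_bqtn_models = n_models_total, burden = burden))
}
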