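#' Construct a genotype matrix
#'
#' Container pairing an n x m additive dosage matrix (individuals x SNPs,
#' values in [0, 2], NA allowed) with per-SNP metadata. Minor allele
#' frequencies are computed from the dosages at construction.
#'
#' @param dosage numeric matrix with individual ids as rownames and SNP ids
#'   as colnames.
#' @param snps optional data frame of per-SNP metadata with at least an `id`
#'   column matching `colnames(dosage)`; `chrom`, `pos` and a logical
#'   `coding` column are carried along when present.
#' @return A list of class `"genotype_matrix"` with elements `dosage` and
#'   `snps` (id, chrom, pos, maf, coding).
#' @export
genotype_matrix <- function(dosage, snps = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)), !is.null(colnames(dosage)))
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(snps)) {
    snps <- data.frame(id = colnames(dosage), stringsAsFactors = FALSE)
  }
  stopifnot(identical(as.character(snps$id), colnames(dosage)))
  if (is.null(snps$chrom)) snps$chrom <- "8"
  if (is.null(snps$pos)) snps$pos <- seq_len(ncol(dosage))
  if (is.null(snps$coding)) snps$coding <- FALSE
  af <- colMeans(dosage, na.rm = TRUE) / 2
  snps$maf <- pmin(af, 1 - af)
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  cat("  MAF range:", paste(signif(range(x$snps$maf), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Minor allele frequencies
#'
#' @param genotypes a [genotype_matrix()].
#' @return Named numeric vector of per-SNP MAFs (from the stored metadata).
#' @export
maf <- function(genotypes) {
  stats::setNames(genotypes$snps$maf, genotypes$snps$id)
}

#' Check Mendelian consistency of dosages against a pedigree
#'
#' Flags parent-offspring trios whose dosages are unreachable by biallelic
#' transmission: an offspring cannot carry more copies of an allele than the
#' parents can transmit (e.g. parents 0 x 0 cannot produce dosage >= 1, and
#' 2 x 2 cannot produce dosage <= 1).
#'
#' @param genotypes a [genotype_matrix()].
#' @param ped a [pedigree()] whose ids index rows of the dosage matrix.
#' @return A data frame of violations (id, snp, dosage, father_dosage,
#'   mother_dosage); zero rows when the data are consistent.
#' @export
check_mendelian <- function(genotypes, ped) {
  G <- round(genotypes$dosage)
  kids <- which(!is.na(ped$father))
  out <- list()
  for (i in kids) {
    g <- G[ped$id[i], ]
    gf <- G[ped$father[i], ]
    gm <- G[ped$mother[i], ]
    # transmissible copies of the alternate allele per parent: 0->{0}, 1->{0,1}, 2->{1}
    lo <- pmax(gf - 1, 0) + pmax(gm - 1, 0)
    hi <- pmin(gf, 1) + pmin(gm, 1)
    bad <- which(!is.na(g) & !is.na(lo) & (g < lo | g > hi))
    if (length(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        id = ped$id[i], snp = colnames(G)[bad], dosage = g[bad],
        father_dosage = gf[bad], mother_dosage = gm[bad],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id = character(), snp = character(), dosage = numeric(),
                      father_dosage = numeric(), mother_dosage = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write genotypes as a dosage TSV
#'
#' Headered tab-separated table: first column `id`, one column per SNP.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes$dosage),
                   genotypes$dosage, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as VCF 4.2 with a DS (dosage) FORMAT field
#'
#' One biallelic record per SNP (REF A, ALT G placeholders), 1-based
#' positions from the SNP metadata, and per-sample `GT:DS` entries; GT is the
#' rounded dosage. Missing dosages are written as `./.:.`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path (plain text, uncompressed).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  G <- genotypes$dosage
  meta <- genotypes$snps
  samples <- rownames(G)
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Additive dosage of the alternate allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_codes <- c("0/0", "0/1", "1/1")
  recs <- vapply(seq_len(ncol(G)), function(k) {
    ds <- G[, k]
    gt <- ifelse(is.na(ds), "./.", gt_codes[pmin(pmax(round(ds), 0), 2) + 1L])
    dss <- ifelse(is.na(ds), ".", format(ds, trim = TRUE, digits = 6))
    paste(c(meta$chrom[k], meta$pos[k], meta$id[k], "A", "G", ".", "PASS", ".",
            "GT:DS", paste(gt, dss, sep = ":")), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF reading uses VariantAnnotation; the per-sample `DS` field is used when
#' present and otherwise dosages are obtained by summing `GT` alleles.
#' Multiallelic records are dropped with a message. The dosage-TSV branch
#' reads the headered layout written by [write_genotypes_tsv()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension/sniffing), `"vcf"` or `"dosage"`.
#' @param samples optional character vector; when given, the sample set must
#'   match it exactly (order-insensitive) or an error listing the offenders
#'   is raised.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           samples = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else {
      first <- readLines(path, n = 1L)
      if (startsWith(first, "##fileformat=VCF")) "vcf" else "dosage"
    }
  }
  if (format == "vcf") {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stop("reading VCF requires the VariantAnnotation package")
    }
    v <- VariantAnnotation::readVcf(path)
    multi <- lengths(VariantAnnotation::alt(v)) != 1L
    if (any(multi)) {
      message(sum(multi), " multiallelic record(s) dropped")
      v <- v[!multi]
    }
    gen <- VariantAnnotation::geno(v)
    if ("DS" %in% names(gen)) {
      D <- gen$DS
      mode(D) <- "numeric"
    } else if ("GT" %in% names(gen)) {
      gt <- gen$GT
      D <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
      D[gt %in% c("0/0", "0|0")] <- 0
      D[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
      D[gt %in% c("1/1", "1|1")] <- 2
    } else {
      stop("VCF has neither DS nor GT FORMAT fields: ", path)
    }
    rr <- SummarizedExperiment::rowRanges(v)
    meta <- data.frame(
      id = names(rr),
      chrom = as.character(GenomeInfoDb::seqnames(rr)),
      pos = BiocGenerics::start(rr),
      stringsAsFactors = FALSE)
    dos <- t(D)
    colnames(dos) <- meta$id
  } else {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
    ids <- as.character(df[[1]])
    dos <- as.matrix(df[, -1, drop = FALSE])
    rownames(dos) <- ids
    meta <- NULL
  }
  if (!is.null(samples)) {
    extra <- setdiff(rownames(dos), samples)
    miss <- setdiff(samples, rownames(dos))
    if (length(extra) || length(miss)) {
      stop("sample mismatch with pedigree; missing: [",
           paste(miss, collapse = ", "), "] unexpected: [",
           paste(extra, collapse = ", "), "]")
    }
    dos <- dos[samples, , drop = FALSE]
  }
  genotype_matrix(dos, snps = meta)
}
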