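#' Theoretical kinship from a pedigree
#'
#' Computes the matrix of kinship coefficients phi_ij by the standard
#' recursion: founders are mutually unrelated with phi_ii = 1/2; for a
#' non-founder i with parents (f, m), phi_ij = (phi_fj + phi_mj)/2 for any
#' previously placed j, and phi_ii = (1 + phi_fm)/2 (so inbreeding raises the
#' diagonal). Twice this matrix, 2*Phi, is the expected additive genetic
#' relationship matrix used as a random-effect kernel throughout.
#'
#' @param ped a [pedigree()].
#' @return An n x n symmetric matrix of class `"kinship_matrix"` with the
#'   individual ids as dimnames and attribute `provenance = "pedigree"`.
#' @examples
#' ped <- pedigree(fam = "f", id = c("a", "b", "c"),
#'                 father = c(NA, NA, "a"), mother = c(NA, NA, "b"),
#'                 sex = c(1, 2, 1))
#' pedigree_kinship(ped)["a", "c"] # parent-offspring: 0.25
#' @export
pedigree_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree") || is.data.frame(ped))
  n <- nrow(ped)
  ids <- ped$id
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  ord <- .pedigree_order(ped)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  placed <- logical(n)
  for (i in ord) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      j <- which(placed)
      if (length(j)) {
        v <- 0.5 * (phi[fa[i], j] + phi[mo[i], j])
        phi[i, j] <- v
        phi[j, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
    placed[i] <- TRUE
  }
  new_kinship_matrix(phi, provenance = "pedigree")
}

new_kinship_matrix <- function(mat, provenance, snps = NULL, ridge = 0) {
  structure(mat,
            class = c("kinship_matrix", "matrix", "array"),
            provenance = provenance, snps = snps, ridge = ridge)
}

#' Empirical kinship from SNP dosages
#'
#' Allele-frequency-standardized genetic relationship matrix on the kinship
#' scale: E_ij = (1/2m) * sum_k (x_ik - 2 p_k)(x_jk - 2 p_k) / (2 p_k (1 - p_k))
#' over the m polymorphic SNPs of the subset, so that 2E is directly
#' comparable with 2*Phi from [pedigree_kinship()]. Monomorphic SNPs are
#' dropped with a warning; missing dosages are replaced by the SNP mean
#' (equivalently, they contribute zero to the centered cross-product).
#'
#' @param genotypes a [genotype_matrix()].
#' @param snps optional character vector of SNP ids restricting the subset
#'   (default: all SNPs).
#' @param freq_from `"all"` (default) estimates allele frequencies from every
#'   individual; `"founders"` uses pedigree founders only (requires `ped`).
#' @param ped pedigree, only needed for `freq_from = "founders"`.
#' @param style `"standardized"` (default, as above) or `"covariance"`, a
#'   dialect switch replacing the per-SNP 1/(2p(1-p)) weight by the average
#'   heterozygosity normalizer of a raw-covariance GRM.
#' @param condition if TRUE (default), a ridge `delta * I` with the smallest
#'   delta restoring positive semi-definiteness is added; delta is stored in
#'   the `"ridge"` attribute and reported via a message when nonzero.
#' @return A `"kinship_matrix"` with `provenance = "empirical"` and the SNP
#'   ids used in the `"snps"` attribute.
#' @export
empirical_kinship <- function(genotypes, snps = NULL,
                              freq_from = c("all", "founders"), ped = NULL,
                              style = c("standardized", "covariance"),
                              condition = TRUE) {
  freq_from <- match.arg(freq_from)
  style <- match.arg(style)
  G <- genotypes$dosage
  if (!is.null(snps)) {
    missing_snps <- setdiff(snps, colnames(G))
    if (length(missing_snps)) {
      stop("SNP id(s) not in genotype matrix: ",
           paste(missing_snps, collapse = ", "))
    }
    G <- G[, snps, drop = FALSE]
  }
  rows_for_freq <- seq_len(nrow(G))
  if (freq_from == "founders") {
    if (is.null(ped)) stop("freq_from = 'founders' requires `ped`")
    rows_for_freq <- which(rownames(G) %in% founders(ped))
  }
  p <- colMeans(G[rows_for_freq, , drop = FALSE], na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs in the subset are monomorphic")
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic SNP(s) excluded from empirical kinship: ",
            paste(colnames(G)[!poly], collapse = ", "))
    G <- G[, poly, drop = FALSE]
    p <- p[poly]
  }
  m <- ncol(G)
  Z <- sweep(G, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  if (style == "standardized") {
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    E <- tcrossprod(Z) / (2 * m)
  } else {
    E <- tcrossprod(Z) / (2 * sum(2 * p * (1 - p)))
  }
  ridge <- 0
  if (condition) {
    ev_min <- min(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 0) {
      ridge <- -ev_min + 1e-10
      E <- E + diag(ridge, nrow(E))
      message("empirical kinship conditioned with ridge delta = ",
              format(ridge, digits = 3))
    }
  }
  new_kinship_matrix(E, provenance = "empirical",
                     snps = colnames(G), ridge = ridge)
}

#' Read / write a labeled kinship matrix as TSV
#'
#' Square tab-separated layout with individual ids as both the header row and
#' the first column.
#'
#' @param path file path.
#' @param kin a `"kinship_matrix"` (any square labeled matrix is accepted on
#'   write).
#' @param provenance stored on read (`"pedigree"` or `"empirical"`).
#' @export
write_kinship <- function(kin, path) {
  df <- data.frame(id = rownames(kin), as.data.frame(unclass(kin)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path, provenance = "pedigree") {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  if (!identical(rownames(mat), colnames(mat))) {
    stop("kinship TSV row/column labels disagree: ", path)
  }
  new_kinship_matrix(mat, provenance = provenance)
}
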