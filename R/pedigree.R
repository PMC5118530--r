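#' Construct a pedigree table
#'
#' A pedigree is a data frame with one row per individual and columns
#' `fam` (family id), `id` (individual id, unique across the whole table),
#' `father`, `mother` (ids of the parents, `NA` for founders) and `sex`
#' (1 = male, 2 = female, the usual FAM coding). Parentage must be acyclic
#' and, by default, both parents must be known or both unknown.
#'
#' @param fam,id,father,mother character vectors (recycled where sensible);
#'   `"0"` and `""` in the parent columns are read as missing.
#' @param sex integer vector, 1 = male, 2 = female.
#' @return A validated data frame of class `"pedigree"`.
#' @seealso [read_pedigree()], [pedigree_kinship()], [simulate_pedigrees()]
#' @export
pedigree <- function(fam, id, father = NA_character_, mother = NA_character_, sex) {
  df <- data.frame(
    fam = as.character(fam),
    id = as.character(id),
    father = as.character(father),
    mother = as.character(mother),
    sex = as.integer(sex),
    stringsAsFactors = FALSE
  )
  validate_pedigree(df)
}

#' Validate a pedigree data frame
#'
#' Checks id uniqueness, parent references (existence, same family, sex
#' consistent with the parental role), the both-or-neither parent policy,
#' and acyclicity of the parentage graph.
#'
#' @param df data frame with columns fam, id, father, mother, sex.
#' @param require_both_parents reject individuals with exactly one known
#'   parent (default TRUE).
#' @return `df` with class `"pedigree"` prepended.
#' @export
validate_pedigree <- function(df, require_both_parents = TRUE) {
  stopifnot(is.data.frame(df))
  need <- c("fam", "id", "father", "mother", "sex")
  if (!all(need %in% names(df))) {
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  }
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_
  if (anyDuplicated(df$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (!all(df$sex %in% c(1L, 2L))) {
    stop("sex must be coded 1 (male) / 2 (female)")
  }
  half <- xor(is.na(df$father), is.na(df$mother))
  if (require_both_parents && any(half)) {
    stop("individual(s) with exactly one known parent: ",
         paste(df$id[half], collapse = ", "))
  }
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  bad_fa <- !is.na(df$father) & is.na(fa)
  bad_mo <- !is.na(df$mother) & is.na(mo)
  if (any(bad_fa | bad_mo)) {
    stop("unknown parent id(s) referenced by: ",
         paste(df$id[bad_fa | bad_mo], collapse = ", "))
  }
  ok_fam <- is.na(fa) | df$fam[fa] == df$fam
  ok_fam2 <- is.na(mo) | df$fam[mo] == df$fam
  if (!all(ok_fam & ok_fam2)) {
    stop("parent(s) recorded in a different family for: ",
         paste(df$id[!(ok_fam & ok_fam2)], collapse = ", "))
  }
  if (any(df$sex[stats::na.omit(fa)] != 1L)) stop("father(s) with sex != 1")
  if (any(df$sex[stats::na.omit(mo)] != 2L)) stop("mother(s) with sex != 2")
  .pedigree_order(df) # errors on cycles
  class(df) <- unique(c("pedigree", class(df)))
  df
}

#' Generation depth of each pedigree member
#'
#' 0 for founders, 1 + max(parent depths) otherwise; errors on cyclic
#' parentage.
#'
#' @param df a [pedigree()] (or compatible data frame).
#' @return Integer vector aligned with the rows of `df`.
#' @export
pedigree_depth <- function(df) {
  n <- nrow(df)
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  depth <- rep(NA_integer_, n)
  depth[is.na(fa) & is.na(mo)] <- 0L
  for (iter in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progressed <- FALSE
    for (i in todo) {
      dfa <- if (is.na(fa[i])) 0L else depth[fa[i]]
      dmo <- if (is.na(mo[i])) 0L else depth[mo[i]]
      if (!is.na(dfa) && !is.na(dmo)) {
        depth[i] <- max(dfa, dmo) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed) {
      stop("cyclic parentage involving: ",
           paste(df$id[is.na(depth)], collapse = ", "))
    }
  }
  depth
}

# Topological order (parents before offspring).
.pedigree_order <- function(df) {
  order(pedigree_depth(df), seq_len(nrow(df)))
}

#' Founders of a pedigree
#'
#' @param ped a [pedigree()].
#' @return Character vector of ids with no recorded parents.
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$father) & is.na(ped$mother)]
}

#' Read / write FAM-style pedigree files
#'
#' Tab-separated with columns family, id, father, mother, sex; `0` denotes a
#' missing parent. A header line (`fam\tid\t...`) is written and auto-detected
#' on read, so both headered and classic headerless FAM files parse.
#'
#' @param path file path.
#' @return `read_pedigree()` returns a validated [pedigree()];
#'   `write_pedigree()` returns `path` invisibly.
#' @export
read_pedigree <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^fam\t", first)
  df <- utils::read.delim(path, header = has_header,
                          colClasses = "character", comment.char = "#")
  if (!has_header) {
    if (ncol(df) < 5L) stop("expected >= 5 columns in FAM-style file: ", path)
    df <- df[, 1:5]
    names(df) <- c("fam", "id", "father", "mother", "sex")
  }
  df$sex <- as.integer(df$sex)
  validate_pedigree(df)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)[, c("fam", "id", "father", "mother", "sex")]
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
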