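#' Parse a PED-style pedigree file
#'
#' Reads a whitespace-delimited pedigree file with columns family id,
#' individual id, father id, mother id and sex (1 = male, 2 = female,
#' anything else = unknown). A parent id of \code{"0"} marks a missing
#' parent; founders have both parents missing.
#'
#' @param path Path to the pedigree file.
#' @param header Logical; does the file carry a header row? Default
#'   \code{FALSE}, the usual LINKAGE convention.
#' @return A \code{fam_pedigree}: a data frame with columns \code{fid},
#'   \code{iid}, \code{father}, \code{mother} (both \code{NA} for founders)
#'   and \code{sex}, validated by [as_pedigree()].
#' @seealso [kinship_matrix()], [simulate_pedigree()]
#' @export
parse_pedigree <- function(path, header = FALSE) {
  df <- utils::read.table(path, header = header, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 5L)
    stop("pedigree file must have at least 5 columns (FID IID FATHER MOTHER SEX)")
  df <- df[, 1:5]
  names(df) <- c("fid", "iid", "father", "mother", "sex")
  as_pedigree(df)
}

#' Validate a pedigree data frame
#'
#' Checks the structural invariants a pedigree must satisfy before kinship
#' can be computed: unique individual ids, parents either both missing
#' (founder) or both present in the same family, and an acyclic
#' parent-child graph.
#'
#' @param df Data frame with columns \code{fid}, \code{iid}, \code{father},
#'   \code{mother}, \code{sex}; parent entries \code{"0"}, \code{""} or
#'   \code{NA} count as missing.
#' @return The validated data frame with class \code{fam_pedigree}; missing
#'   parents are normalised to \code{NA} and sex to integer 1/2/\code{NA}.
#' @export
as_pedigree <- function(df) {
  req <- c("fid", "iid", "father", "mother", "sex")
  if (!all(req %in% names(df)))
    stop("pedigree needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df[, req], stringsAsFactors = FALSE)
  for (cl in req[1:4]) df[[cl]] <- as.character(df[[cl]])
  miss <- function(x) is.na(x) | x == "0" | x == ""
  df$father[miss(df$father)] <- NA_character_
  df$mother[miss(df$mother)] <- NA_character_
  sx <- suppressWarnings(as.integer(df$sex))
  sx[!sx %in% c(1L, 2L)] <- NA_integer_
  df$sex <- sx

  if (anyDuplicated(df$iid))
    stop("duplicate individual ids: ",
         paste(unique(df$iid[duplicated(df$iid)]), collapse = ", "))
  one_parent <- xor(is.na(df$father), is.na(df$mother))
  if (any(one_parent))
    stop("individuals with exactly one known parent (row ",
         paste(which(one_parent), collapse = ", "),
         "): both parents must be known or both missing")

  fa <- match(df$father, df$iid)
  mo <- match(df$mother, df$iid)
  bad_fa <- !is.na(df$father) & is.na(fa)
  bad_mo <- !is.na(df$mother) & is.na(mo)
  if (any(bad_fa | bad_mo)) {
    row <- which(bad_fa | bad_mo)[1L]
    stop("row ", row, ": parent id not found in pedigree (",
         df$father[row], "/", df$mother[row], ")")
  }
  nonf <- which(!is.na(fa))
  if (any(df$fid[fa[nonf]] != df$fid[nonf]) ||
      any(df$fid[mo[nonf]] != df$fid[nonf]))
    stop("parents must belong to the same family as their offspring")

  if (is.null(pedigree_order_or_null(df)))
    stop("pedigree contains a cycle: some individual is its own ancestor")

  class(df) <- c("fam_pedigree", "data.frame")
  rownames(df) <- NULL
  df
}

# Topological order (parents before children), or NULL if cyclic.
pedigree_order_or_null <- function(df) {
  n <- nrow(df)
  fa <- match(df$father, df$iid)
  mo <- match(df$mother, df$iid)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  parent_ok <- function(p, cand) is.na(p[cand]) |
    placed[ifelse(is.na(p[cand]), 1L, p[cand])]
  repeat {
    cand <- which(!placed)
    ready <- cand[parent_ok(fa, cand) & parent_ok(mo, cand)]
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) NULL else ord
}

#' Founder indicator
#' @param ped A \code{fam_pedigree}.
#' @return Logical vector, \code{TRUE} for individuals with no recorded parents.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' Kinship matrix from a pedigree
#'
#' Computes the kinship coefficient phi for every pair of individuals with
#' the standard recursion, evaluated in topological (parents-first) order:
#' founders have phi_ii = 0.5 and phi = 0 with every earlier individual;
#' a non-founder i with parents f and m has phi_ii = 0.5 (1 + phi_fm) and
#' phi_ij = 0.5 (phi_fj + phi_mj) for every individual j placed before i.
#' Inbreeding is handled by the recursion as written (phi_ii may exceed 0.5).
#' Individuals from different families have kinship 0, so the matrix is
#' block-diagonal by family. The additive genetic covariance kernel used by
#' the mixed models is \code{2 * K * sigma_g^2}.
#'
#' @param ped A \code{fam_pedigree}.
#' @return Symmetric numeric matrix of kinship coefficients with individual
#'   ids as dimnames, in the pedigree's row order.
#' @examples
#' trio <- as_pedigree(data.frame(
#'   fid = "1", iid = c("F", "M", "C"),
#'   father = c(NA, NA, "F"), mother = c(NA, NA, "M"), sex = c(1, 2, 1)))
#' kinship_matrix(trio)["F", "C"]  # 0.25
#' @export
kinship_matrix <- function(ped) {
  ped <- if (inherits(ped, "fam_pedigree")) ped else as_pedigree(ped)
  n <- nrow(ped)
  ord <- pedigree_order_or_null(ped)
  fa <- match(ped$father, ped$iid)
  mo <- match(ped$mother, ped$iid)
  K <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  seen <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
      # founder: kinship 0 with all previously placed individuals
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      if (length(seen)) {
        kij <- 0.5 * (K[fa[i], seen] + K[mo[i], seen])
        K[i, seen] <- kij
        K[seen, i] <- kij
      }
    }
    seen <- c(seen, i)
  }
  K
}

#' Write / read a kinship matrix as square TSV
#'
#' The file has individual ids as both the header row and the first column.
#' @param K Square kinship matrix with dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- as.character(df[[1]])
  storage.mode(K) <- "double"
  K
}

# Family id of each sample id, resolved through the pedigree.
family_of <- function(ids, ped) {
  idx <- match(ids, ped$iid)
  if (anyNA(idx))
    stop("sample ids absent from pedigree: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  ped$fid[idx]
}
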