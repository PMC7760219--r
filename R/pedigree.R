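#' Read a pedigree file
#'
#' Reads a three-column delimited text file (individual, sire, dam).
#' `"0"`, the empty string and `NA` all denote an unknown parent.
#'
#' @param path Path to the pedigree file.
#' @param delim Field delimiter (default whitespace/tab).
#' @param header Whether the file has a header line.
#' @return A tibble with columns `id`, `sire`, `dam` (character; `NA` =
#'   unknown parent).
#' @export
read_pedigree <- function(path, delim = "\t", header = TRUE) {
  df <- utils::read.delim(path, sep = delim, header = header,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3) stop("pedigree file must have at least 3 columns")
  ped <- tibble::tibble(id = df[[1]], sire = df[[2]], dam = df[[3]])
  ped$sire[ped$sire %in% c("0", "")] <- NA_character_
  ped$dam[ped$dam %in% c("0", "")] <- NA_character_
  ped
}

# Validate a pedigree data frame and return a canonical form:
# character ids, NA for unknown parents, plus a topological ordering
# (parents before offspring).  Errors on duplicated ids, references to
# absent individuals, and cycles.
ped_normalize <- function(ped) {
  ped <- as.data.frame(ped)
  if (ncol(ped) < 3) stop("pedigree needs columns id, sire, dam")
  out <- tibble::tibble(id = as.character(ped[[1]]),
                        sire = as.character(ped[[2]]),
                        dam = as.character(ped[[3]]))
  out$sire[out$sire %in% c("0", "")] <- NA_character_
  out$dam[out$dam %in% c("0", "")] <- NA_character_
  if (anyDuplicated(out$id))
    stop("duplicated individual identifiers in pedigree: ",
         paste(unique(out$id[duplicated(out$id)])[1:3], collapse = ", "))
  bad <- setdiff(c(out$sire, out$dam), c(out$id, NA_character_))
  if (length(bad))
    stop("sire/dam identifiers absent from the pedigree: ",
         paste(head(bad, 5), collapse = ", "))
  out
}

# Kahn-style topological sort; returns an integer permutation of rows.
ped_toposort <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  ord <- integer(0)
  parent_ok <- function(p) {
    ok <- is.na(p)
    ok[!is.na(p)] <- placed[p[!is.na(p)]]
    ok
  }
  while (length(ord) < n) {
    ready <- !placed & parent_ok(si) & parent_ok(di)
    if (!any(ready))
      stop("pedigree contains a cycle (an individual is its own ancestor)")
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  ord
}

# 0-based parent index vectors in topological order plus the permutation.
ped_index <- function(ped) {
  ped <- ped_normalize(ped)
  ord <- ped_toposort(ped)
  sorted <- ped[ord, ]
  list(ped = sorted,
       order = ord,
       sire0 = match(sorted$sire, sorted$id, nomatch = 0L) - 1L,
       dam0 = match(sorted$dam, sorted$id, nomatch = 0L) - 1L)
}

#' Numerator relationship matrix from a pedigree
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: `a_ii = 1 + a_{sd}/2` and `a_ij = (a_{j,s_i} + a_{j,d_i})/2`,
#' with an unknown parent contributing zero.  Unknown parents are treated
#' as unrelated, non-inbred founders.  Input rows need not be sorted;
#' the result is returned in the input row order.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (unknown
#'   parents as `NA`, `""` or `"0"`).
#' @return A symmetric matrix with `dimnames` equal to the ids.
#' @seealso [build_A_inverse()], [inbreeding()]
#' @export
build_A <- function(ped) {
  px <- ped_index(ped)
  A <- build_A_cpp(px$sire0, px$dam0)
  dimnames(A) <- list(px$ped$id, px$ped$id)
  ids <- ped_normalize(ped)$id
  A[ids, ids, drop = FALSE]
}

#' Inbreeding coefficients
#'
#' Computes per-individual inbreeding coefficients F (diagonal of A minus
#' one) by the Meuwissen-Luo recursion, without forming A.
#'
#' @inheritParams build_A
#' @return Named numeric vector of F in input order.
#' @export
inbreeding <- function(ped) {
  px <- ped_index(ped)
  f <- inbreeding_cpp(px$sire0, px$dam0)
  names(f) <- px$ped$id
  f[ped_normalize(ped)$id]
}

#' Inverse numerator relationship matrix by Henderson's rules
#'
#' Assembles A-inverse directly from the pedigree with per-individual
#' Mendelian-sampling variances `d_i = 1/2 - (F_s + F_d)/4` (an unknown
#' parent enters with F = -1, giving the classic 1, 3/4, 1/2 values for
#' zero, one or two known non-inbred parents).  Inbreeding coefficients
#' are computed, not assumed zero.
#'
#' @inheritParams build_A
#' @return A symmetric matrix, inverse of [build_A()]'s output.
#' @export
build_A_inverse <- function(ped) {
  px <- ped_index(ped)
  f <- inbreeding_cpp(px$sire0, px$dam0)
  Ai <- ainverse_cpp(px$sire0, px$dam0, f)
  dimnames(Ai) <- list(px$ped$id, px$ped$id)
  ids <- ped_normalize(ped)$id
  Ai[ids, ids, drop = FALSE]
}

#' Restrict a pedigree to a set of individuals and their ancestors
#'
#' Relationships among the kept individuals are unchanged by pruning,
#' since additive relationships flow only through ancestors.  Used to
#' extract the sire block of A cheaply from a large pedigree.
#'
#' @inheritParams build_A
#' @param keep Character vector of ids to keep (with all their ancestors).
#' @return The pruned pedigree tibble (topologically ordered).
#' @export
prune_ancestors <- function(ped, keep) {
  ped <- ped_normalize(ped)
  missing <- setdiff(keep, ped$id)
  if (length(missing))
    stop("ids not in pedigree: ", paste(head(missing, 5), collapse = ", "))
  wanted <- unique(as.character(keep))
  repeat {
    rows <- ped[ped$id %in% wanted, ]
    parents <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), wanted)
    if (!length(parents)) break
    wanted <- c(wanted, parents)
  }
  px <- ped_index(ped[ped$id %in% wanted, ])
  px$ped
}

# Sire-block of A (and its inverse) for the genetic effect of a sire
# model.  `scheme = "full"` uses the whole pedigree (pruned to the sires'
# ancestors, which leaves the sire block identical); `"sires_only"`
# discards dam links so relationships flow through the sire line only.
sire_relationship <- function(ped, sires, scheme = c("full", "sires_only")) {
  scheme <- match.arg(scheme)
  ped <- ped_normalize(ped)
  if (scheme == "sires_only") ped$dam <- NA_character_
  pruned <- prune_ancestors(ped, sires)
  A <- build_A(pruned)
  Ass <- A[sires, sires, drop = FALSE]
  list(A = Ass, Ainv = chol2inv(chol(Ass)))
}
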