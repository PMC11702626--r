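#' Conservative-substitution groups
#'
#' Defines which amino-acid replacements count as "conservative" when a
#' conservation window is allowed a single similar-residue substitution.
#' Two schemes are available:
#'
#' * `"classic"`: disjoint physicochemical classes
#'   \{I,L,V,M\}, \{F,W,Y\}, \{K,R,H\}, \{D,E\}, \{S,T\}, \{N,Q\}, \{A,G\}.
#'   A replacement is conservative iff the two residues differ and share a
#'   class.
#' * `"blosum62_positive"`: a replacement is conservative iff the two residues
#'   differ and their BLOSUM62 score is strictly positive.
#'
#' A residue is never a conservative substitution of itself, and the relation
#' is symmetric under both schemes.
#'
#' @param scheme Character; `"classic"` (default) or `"blosum62_positive"`.
#' @param groups Optional list of character vectors of single residues,
#'   overriding the built-in classes. Groups must be pairwise disjoint.
#' @return An object of class `similarity_groups`.
#' @examples
#' sg <- similarity_groups()
#' is_conservative(sg, "I", "L")
#' is_conservative(sg, "I", "I")
#' @export
similarity_groups <- function(scheme = c("classic", "blosum62_positive"),
                              groups = NULL) {
  scheme <- match.arg(scheme)
  pair_ok <- matrix(FALSE, 26L, 26L, dimnames = list(LETTERS, LETTERS))
  if (!is.null(groups) || scheme == "classic") {
    groups <- groups %||% list(
      c("I", "L", "V", "M"),
      c("F", "W", "Y"),
      c("K", "R", "H"),
      c("D", "E"),
      c("S", "T"),
      c("N", "Q"),
      c("A", "G")
    )
    all_res <- unlist(groups)
    if (anyDuplicated(all_res)) {
      abort("similarity groups must be pairwise disjoint")
    }
    for (g in groups) {
      pair_ok[g, g] <- TRUE
    }
    scheme <- "classic"
  } else {
    b62 <- substitution_matrix("BLOSUM62")
    res <- intersect(rownames(b62), LETTERS)
    pair_ok[res, res] <- b62[res, res] > 0
    groups <- NULL
  }
  diag(pair_ok) <- FALSE
  structure(
    list(scheme = scheme, groups = groups, pair_ok = pair_ok),
    class = "similarity_groups"
  )
}

#' Test residue pairs for conservative substitution
#'
#' Vectorised over `a` and `b` (single-character residue codes). Characters
#' outside `A`-`Z` (gap or padding symbols) are never conservative.
#'
#' @param groups A [similarity_groups()] object.
#' @param a,b Character vectors of single residues.
#' @return Logical vector.
#' @export
is_conservative <- function(groups, a, b) {
  stopifnot(inherits(groups, "similarity_groups"))
  ia <- match(toupper(a), LETTERS)
  ib <- match(toupper(b), LETTERS)
  out <- rep(FALSE, length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- groups$pair_ok[cbind(ia[ok], ib[ok])]
  out
}

#' @export
print.similarity_groups <- function(x, ...) {
  cat("<similarity_groups> scheme:", x$scheme, "\n")
  if (!is.null(x$groups)) {
    cat(paste0("  {", vapply(x$groups, paste, "", collapse = ","), "}"),
        sep = "\n")
  }
  invisible(x)
}
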