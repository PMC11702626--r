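#' Alignment scoring scheme
#'
#' Bundles a symmetric substitution matrix with affine gap penalties for
#' [align_global()]. A gap of length `k` costs `gap_open` for its first
#' column plus `gap_extend` for each additional column; a gap in the other
#' row always opens a new gap. Residues absent from the matrix (e.g. U, or
#' ambiguity codes when a reduced matrix is supplied) are scored at the
#' matrix minimum.
#'
#' The default (BLOSUM62, open -10, extend -0.5) is the de-facto standard
#' for global protein alignment. Downstream conservation calls use identity
#' within windows, so results are robust to any reasonable scheme, but the
#' scheme is pinned so alignments are reproducible.
#'
#' @param matrix A matrix name available in \pkg{Biostrings}
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`) or a symmetric numeric
#'   matrix with single-letter dimnames.
#' @param gap_open Penalty (<= 0) for the first column of a gap.
#' @param gap_extend Penalty (<= 0) for each additional gap column.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme("BLOSUM45", gap_open = -12, gap_extend = -1)
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -10,
                           gap_extend = -0.5) {
  if (is.character(matrix)) {
    name <- matrix
    matrix <- substitution_matrix(name)
  } else {
    name <- "custom"
  }
  if (!is.matrix(matrix) || !is.numeric(matrix) ||
      is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix))) {
    abort("`matrix` must be a named numeric matrix with identical row/col names")
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    abort("substitution matrix must be symmetric")
  }
  if (!is.finite(gap_open) || !is.finite(gap_extend) ||
      gap_open > 0 || gap_extend > 0) {
    abort("gap penalties must be finite and <= 0")
  }
  structure(
    list(matrix = matrix, matrix_name = name,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

# Fetch a substitution matrix shipped with Biostrings by name.
substitution_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch(
    {
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    },
    warning = function(w) FALSE,
    error = function(e) FALSE
  )
  if (!ok || is.null(e[[name]])) {
    abort(paste0("unknown substitution matrix: ", name))
  }
  e[[name]]
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme>", x$matrix_name,
      sprintf("gap_open=%g gap_extend=%g\n", x$gap_open, x$gap_extend))
  invisible(x)
}
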