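#' Global pairwise protein alignment
#'
#' Optimal-score global (end-gap-penalised) alignment of two protein
#' sequences under affine gap penalties, via the Needleman-Wunsch/Gotoh
#' three-state recursion. Traceback tie-breaks are pinned (diagonal over up
#' over left, match state preferred at equal score) so the returned
#' alignment is bit-reproducible. Residues absent from the substitution
#' matrix are scored at the matrix minimum.
#'
#' @param source_seq,target_seq Non-empty uppercase residue strings
#'   (no gap characters).
#' @param scheme A [scoring_scheme()]; default BLOSUM62 with gap open -10,
#'   extend -0.5.
#' @param source_accession,target_accession Optional labels carried into
#'   the result.
#' @return An object of class `protein_alignment`: list with
#'   `aligned_source`, `aligned_target` (equal-length strings over residues
#'   plus `-`; no column is a gap in both rows), `score`,
#'   `source_accession`, `target_accession`.
#' @examples
#' aln <- align_global("HEAGAWGHEE", "PAWHEAE")
#' aln
#' @export
align_global <- function(source_seq, target_seq, scheme = scoring_scheme(),
                         source_accession = NA_character_,
                         target_accession = NA_character_) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  for (s in c(source_seq, target_seq)) {
    if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
      abort("sequences must be non-empty strings")
    }
    if (grepl("[^A-Za-z]", s)) {
      abort("sequences must contain residues only (no gaps or padding)")
    }
  }
  a <- toupper(source_seq)
  b <- toupper(target_seq)
  codes_a <- encode_residues(a, scheme$matrix)
  codes_b <- encode_residues(b, scheme$matrix)
  raw <- gotoh_align_c(codes_a, codes_b, scheme$matrix,
                       scheme$gap_open, scheme$gap_extend)
  ops <- raw$ops
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  row_a <- rep("-", length(ops))
  row_a[ops != 3L] <- ca
  row_b <- rep("-", length(ops))
  row_b[ops != 2L] <- cb
  structure(
    list(
      aligned_source = paste(row_a, collapse = ""),
      aligned_target = paste(row_b, collapse = ""),
      score = raw$score,
      source_accession = source_accession,
      target_accession = target_accession,
      scheme_name = scheme$matrix_name
    ),
    class = "protein_alignment"
  )
}

encode_residues <- function(s, mat) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], rownames(mat))
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' @export
print.protein_alignment <- function(x, width = 60, ...) {
  cat(sprintf("<protein_alignment> score %.1f (%s)\n", x$score, x$scheme_name))
  n <- nchar(x$aligned_source)
  for (start in seq(1, n, by = width)) {
    end <- min(start + width - 1, n)
    a <- substr(x$aligned_source, start, end)
    b <- substr(x$aligned_target, start, end)
    mid <- paste(ifelse(
      strsplit(a, "")[[1]] == strsplit(b, "")[[1]] &
        strsplit(a, "")[[1]] != "-", "|", " "
    ), collapse = "")
    cat(a, mid, b, "", sep = "\n")
  }
  invisible(x)
}

# Split an alignment into column vectors plus running residue coordinates
# (0 where a row has a gap at that column).
alignment_columns <- function(aln) {
  sa <- strsplit(aln$aligned_source, "", fixed = TRUE)[[1]]
  ta <- strsplit(aln$aligned_target, "", fixed = TRUE)[[1]]
  list(
    source = sa, target = ta,
    source_pos = cumsum(sa != "-"),
    target_pos = cumsum(ta != "-")
  )
}

#' Project a source coordinate through an alignment
#'
#' Maps a 1-based residue position on the ungapped source sequence to the
#' aligned target coordinate.
#'
#' @param aln A `protein_alignment`.
#' @param source_pos 1-based position on the ungapped source.
#' @return List with `target_pos` (1-based target residue position, or `NA`
#'   when the source residue is aligned to a gap) and `column_index`
#'   (1-based alignment column).
#' @export
project_position <- function(aln, source_pos) {
  cols <- alignment_columns(aln)
  n_src <- max(cols$source_pos)
  if (source_pos < 1L || source_pos > n_src) {
    abort("`source_pos` is outside the ungapped source sequence")
  }
  col <- which(cols$source != "-" & cols$source_pos == source_pos)
  list(
    target_pos = if (cols$target[col] == "-") NA_integer_
                 else as.integer(cols$target_pos[col]),
    column_index = as.integer(col)
  )
}

#' Extract the aligned span of a source window
#'
#' Returns the alignment columns spanning a contiguous window of the
#' ungapped source sequence (interior target-insertion columns included).
#'
#' @param aln A `protein_alignment`.
#' @param source_start 1-based start on the ungapped source.
#' @param length Window length in source residues (>= 1).
#' @return List with `source_window` and `target_window` (alignment rows
#'   over the spanned columns, `-` included) and `has_gap` (`TRUE` if any
#'   spanned column carries a gap in either row).
#' @export
extract_aligned_window <- function(aln, source_start, length) {
  cols <- alignment_columns(aln)
  n_src <- max(cols$source_pos)
  if (length < 1L || source_start < 1L || source_start + length - 1L > n_src) {
    abort("window is outside the ungapped source sequence")
  }
  first <- which(cols$source != "-" & cols$source_pos == source_start)
  last <- which(cols$source != "-" & cols$source_pos == source_start + length - 1L)
  span <- first:last
  list(
    source_window = paste(cols$source[span], collapse = ""),
    target_window = paste(cols$target[span], collapse = ""),
    has_gap = any(cols$source[span] == "-") || any(cols$target[span] == "-")
  )
}

#' @rdname tidy.protein_alignment
#' @export
tidy.protein_alignment <- function(x, ...) {
  cols <- alignment_columns(x)
  tibble::tibble(
    column = seq_along(cols$source),
    source = cols$source,
    target = cols$target,
    source_pos = ifelse(cols$source == "-", NA_integer_,
                        as.integer(cols$source_pos)),
    target_pos = ifelse(cols$target == "-", NA_integer_,
                        as.integer(cols$target_pos)),
    match = cols$source == cols$target & cols$source != "-"
  )
}

#' Tidy and summarise a protein alignment
#'
#' `tidy()` returns one row per alignment column (residues, running
#' coordinates, identity flag); `glance()` returns a one-row summary
#' (score, length, identity fraction, gap columns).
#'
#' @param x A `protein_alignment`.
#' @param ... Unused.
#' @name tidy.protein_alignment
#' @export
glance.protein_alignment <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    score = x$score,
    columns = nrow(td),
    identity = mean(td$match),
    gap_columns = sum(td$source == "-" | td$target == "-"),
    source_accession = x$source_accession,
    target_accession = x$target_accession
  )
}
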