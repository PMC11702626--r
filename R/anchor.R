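#' Strip terminus padding from a +/-7 flanking peptide
#'
#' Catalog flanking peptides are 15 characters with the phosphosite at the
#' centre (position 8) and `_` padding where the +/-7 window overruns a
#' protein terminus. This removes the padding and reports where the
#' phosphosite sits in the unpadded core.
#'
#' @param flank_peptide A 15-character flanking peptide.
#' @return List with `core_peptide` (padding removed) and `core_site_offset`
#'   (0-based index of the phosphosite within `core_peptide`, i.e.
#'   `7 - number of leading underscores`).
#' @examples
#' unpad_flank("____MKVSYTTPGGT")
#' @export
unpad_flank <- function(flank_peptide) {
  if (nchar(flank_peptide) != 15L) {
    abort("flank peptide must be exactly 15 characters")
  }
  if (!grepl("^_*[A-Z]+_*$", flank_peptide)) {
    abort("flank peptide may carry '_' padding only at its ends")
  }
  n_lead <- nchar(sub("^(_*).*$", "\\1", flank_peptide))
  list(
    core_peptide = gsub("_", "", flank_peptide, fixed = TRUE),
    core_site_offset = 7L - n_lead
  )
}

#' Extract the +/-7 flanking peptide at a protein position
#'
#' Inverse of anchoring: reads the 15-residue window centred on `position`
#' from `sequence`, padding with `_` where the window overruns a terminus.
#'
#' @param sequence Protein sequence (uppercase string).
#' @param position 1-based residue position.
#' @param width Residues on each side of the site (default 7).
#' @return A `2 * width + 1`-character string.
#' @export
flank_at <- function(sequence, position, width = 7L) {
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    abort("`position` is outside the sequence")
  }
  lo <- position - width
  hi <- position + width
  paste0(
    strrep("_", max(0L, 1L - lo)),
    substr(sequence, max(1L, lo), min(n, hi)),
    strrep("_", max(0L, hi - n))
  )
}

# All (possibly overlapping) start positions of `pattern` in `sequence`.
peptide_occurrences <- function(sequence, pattern) {
  hits <- Biostrings::matchPattern(pattern, Biostrings::BString(sequence))
  Biostrings::start(hits)
}

anchor_failure <- function(reason) {
  list(ok = FALSE, reason = reason)
}

#' Anchor a catalog site on its claimed protein
#'
#' Validates one catalog record against the current sequence of the protein
#' it claims (`protein_accession`). The unpadded core of the flanking
#' peptide is searched in the sequence (all overlapping occurrences):
#'
#' * if some occurrence places the phosphosite exactly at the claimed
#'   position, the site anchors there with provenance `"direct"`;
#' * if the peptide occurs at exactly one location but the implied position
#'   differs from the claim, the implied position wins (provenance
#'   `"position_shifted"`): the peptide is the actual immunogen while
#'   catalog coordinates drift across sequence releases;
#' * multiple occurrences, none at the claimed position, fail as
#'   `ambiguous_peptide` -- a guessed anchor would silently corrupt every
#'   downstream alignment window;
#' * no occurrence fails as `peptide_not_found`.
#'
#' Failures are returned as data (`list(ok = FALSE, reason = ...)`), not
#' thrown.
#'
#' @param record One catalog row (list or one-row tibble with `residue`,
#'   `position`, `flank_peptide`).
#' @param sequence The protein sequence for the claimed accession.
#' @return On success `list(ok = TRUE, position, provenance, core_peptide,
#'   core_site_offset)`; otherwise `list(ok = FALSE, reason)` with reason in
#'   `peptide_not_found`, `ambiguous_peptide`, `peptide_too_short`.
#' @export
anchor_direct <- function(record, sequence) {
  core <- unpad_flank(record$flank_peptide)
  if (nchar(core$core_peptide) < 4L) {
    return(anchor_failure("peptide_too_short"))
  }
  occ <- peptide_occurrences(sequence, core$core_peptide)
  if (length(occ) == 0L) {
    return(anchor_failure("peptide_not_found"))
  }
  implied <- occ + core$core_site_offset
  if (!is.na(record$position) && record$position %in% implied) {
    pos <- record$position
    prov <- "direct"
  } else if (length(occ) == 1L) {
    pos <- implied[1]
    prov <- "position_shifted"
  } else {
    return(anchor_failure("ambiguous_peptide"))
  }
  list(ok = TRUE, position = as.integer(pos), provenance = prov,
       core_peptide = core$core_peptide,
       core_site_offset = core$core_site_offset)
}

#' Rescue a site via gene symbol
#'
#' Fallback for records whose accession is absent from (or no longer matches)
#' the current protein release: every protein of the gene(s) matching the
#' record's gene symbol is scanned for an exact occurrence of the unpadded
#' core peptide. When several candidates contain it, the longest candidate
#' wins (ties by lexicographic accession), mirroring the longest-isoform
#' convention; a selected candidate containing the peptide more than once
#' fails as `ambiguous_peptide`.
#'
#' @param record One catalog row.
#' @param candidates Tibble of candidate proteins (`accession`, `sequence`).
#' @return On success `list(ok = TRUE, accession, position,
#'   provenance = "rescued_by_symbol", ...)`; otherwise a failure-reason
#'   list (`accession_not_found` when `candidates` is empty,
#'   `peptide_not_found`, `ambiguous_peptide`).
#' @export
rescue_by_symbol <- function(record, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(anchor_failure("accession_not_found"))
  }
  core <- unpad_flank(record$flank_peptide)
  if (nchar(core$core_peptide) < 4L) {
    return(anchor_failure("peptide_too_short"))
  }
  occs <- lapply(candidates$sequence, peptide_occurrences,
                 pattern = core$core_peptide)
  hit <- lengths(occs) > 0L
  if (!any(hit)) {
    return(anchor_failure("peptide_not_found"))
  }
  cand <- candidates[hit, , drop = FALSE]
  occs <- occs[hit]
  pick <- order(-nchar(cand$sequence), cand$accession)[1]
  if (length(occs[[pick]]) > 1L) {
    return(anchor_failure("ambiguous_peptide"))
  }
  list(ok = TRUE, accession = cand$accession[pick],
       position = as.integer(occs[[pick]][1] + core$core_site_offset),
       provenance = "rescued_by_symbol",
       core_peptide = core$core_peptide,
       core_site_offset = core$core_site_offset)
}

#' Anchor every catalog record against a proteome index
#'
#' Tries [anchor_direct()] on the claimed accession first; records whose
#' accession is missing from the index, or whose peptide no longer matches
#' there, fall through to [rescue_by_symbol()] over all proteins of the
#' record's gene symbol. Every record lands in exactly one bucket: anchored
#' (one output row) or tallied under its failure reason.
#'
#' @param records Catalog tibble from [read_phosphosite_catalog()].
#' @param index A [build_gene_index()] object for the source organism.
#' @return Tibble of anchored sites: the catalog columns plus
#'   `anchored_accession`, `anchored_position`, `provenance`,
#'   `core_peptide`, `core_site_offset`; with attributes `skip_tally`
#'   (named integer by failure reason) and `failures` (tibble of the failed
#'   records and reasons).
#' @export
anchor_sites <- function(records, index) {
  stopifnot(inherits(index, "gene_index"))
  n <- nrow(records)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    out <- NULL
    direct_fail <- NULL
    seq_i <- index_protein(index, rec$protein_accession)
    if (!is.null(seq_i)) {
      a <- anchor_direct(rec, seq_i$sequence)
      if (isTRUE(a$ok)) {
        a$accession <- seq_i$accession
        out <- a
      } else {
        direct_fail <- a$reason
      }
    }
    if (is.null(out)) {
      cand <- index_symbol_proteins(index, rec$gene_symbol)
      a <- rescue_by_symbol(rec, cand)
      if (isTRUE(a$ok)) {
        out <- a
      } else {
        # prefer the more specific direct-path reason over a missing symbol
        reason <- if (a$reason == "accession_not_found" && !is.null(direct_fail))
          direct_fail else a$reason
        out <- anchor_failure(reason)
      }
    }
    res[[i]] <- out
  }
  ok <- vapply(res, function(x) isTRUE(x$ok), logical(1))
  anchored <- records[ok, , drop = FALSE]
  if (any(ok)) {
    anchored$anchored_accession <- vapply(res[ok], `[[`, "", "accession")
    anchored$anchored_position <- vapply(res[ok], `[[`, 1L, "position")
    anchored$provenance <- vapply(res[ok], `[[`, "", "provenance")
    anchored$core_peptide <- vapply(res[ok], `[[`, "", "core_peptide")
    anchored$core_site_offset <- vapply(res[ok], `[[`, 1L, "core_site_offset")
  } else {
    anchored$anchored_accession <- character()
    anchored$anchored_position <- integer()
    anchored$provenance <- character()
    anchored$core_peptide <- character()
    anchored$core_site_offset <- integer()
  }
  reasons <- vapply(res[!ok], `[[`, "", "reason")
  failures <- records[!ok, , drop = FALSE]
  failures$reason <- reasons
  attr(anchored, "skip_tally") <-
    if (length(reasons)) c(table(reasons)) else integer()
  attr(anchored, "failures") <- failures
  anchored
}
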