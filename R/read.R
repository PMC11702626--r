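#' Read a phosphosite catalog
#'
#' Parses a tab-separated phosphosite catalog in the dialect of the
#' PhosphoSitePlus `Phosphorylation_site_dataset` download: any release-note
#' preamble lines before the header are skipped (the header is recognised as
#' the first line containing the modified-residue column name), the modified
#' residue is given as `<AA><position>-p` (e.g. `"S473-p"`), and the
#' `+/-7` flanking peptide is a 15-character window with the phosphosite at
#' its centre (position 8), lowercase in the source dialect, `_`-padded where
#' the window overruns a protein terminus.
#'
#' Rows are kept only when the modification suffix is `-p`, the residue is
#' S/T/Y, the flanking peptide is a valid 15-mer (padding only at the ends),
#' the organism is in `organisms` (when given), and -- if `require_antibody`
#' -- the antibody-catalog cell is non-empty. Rows failing the site or
#' peptide grammar are skipped and counted in the `skip_tally` attribute.
#' Rows whose claimed residue disagrees with the peptide centre are kept but
#' flagged (`center_matches = FALSE`); anchoring adjudicates them later.
#'
#' @param path Path to a tab-separated file (gzip accepted) or literal text.
#' @param organisms Optional character vector of organisms to keep
#'   (case-insensitive); `NULL` keeps all.
#' @param require_antibody Keep only rows with at least one antibody
#'   catalog number (default `FALSE`; the upstream catalog may or may not be
#'   pre-filtered, so this is a switch rather than a hard-coded rule).
#' @param columns Named character vector mapping the roles
#'   `gene`, `accession`, `organism`, `mod_rsd`, `flank`, `antibody` to
#'   header names; defaults to the PhosphoSitePlus names.
#' @return A tibble with columns `gene_symbol`, `protein_accession`,
#'   `organism`, `residue`, `position`, `flank_peptide` (uppercased),
#'   `antibody_ids` (list column), `site_label`, `center_matches`, plus a
#'   `skip_tally` attribute (named integer).
#' @export
read_phosphosite_catalog <- function(path, organisms = NULL,
                                     require_antibody = FALSE,
                                     columns = NULL) {
  columns <- columns %||% c(
    gene = "GENE", accession = "ACC_ID", organism = "ORGANISM",
    mod_rsd = "MOD_RSD", flank = "SITE_+/-7_AA", antibody = "CST_CAT#"
  )
  lines <- readr::read_lines(path)
  hdr <- which(vapply(
    lines,
    function(l) columns[["mod_rsd"]] %in% strsplit(l, "\t", fixed = TRUE)[[1]],
    logical(1), USE.NAMES = FALSE
  ))
  empty <- tibble::tibble(
    gene_symbol = character(), protein_accession = character(),
    organism = character(), residue = character(), position = integer(),
    flank_peptide = character(), antibody_ids = list(),
    site_label = character(), center_matches = logical()
  )
  if (length(lines) == 0 || all(!nzchar(lines))) {
    attr(empty, "skip_tally") <- integer()
    return(empty)
  }
  if (length(hdr) == 0) {
    abort(paste0("catalog header not found: no line contains column `",
                 columns[["mod_rsd"]], "`"))
  }
  hdr <- hdr[1]
  tab <- readr::read_tsv(
    I(paste(lines[hdr:length(lines)], collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, name_repair = "minimal"
  )
  missing <- setdiff(unname(columns), names(tab))
  if (length(missing) > 0) {
    abort(paste0("catalog is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }

  site_label <- trimws(tab[[columns[["mod_rsd"]]]])
  flank_raw <- toupper(trimws(tab[[columns[["flank"]]]]))
  m <- regmatches(site_label, regexec("^([A-Za-z])([0-9]+)-p$", site_label))
  residue <- toupper(vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                            character(1)))
  position <- suppressWarnings(
    as.integer(vapply(m, function(x) if (length(x)) x[3] else NA_character_,
                      character(1)))
  )

  bad_site <- is.na(residue) | is.na(position) | position < 1L
  bad_residue <- !bad_site & !(residue %in% c("S", "T", "Y"))
  bad_flank <- !bad_site & !bad_residue &
    (is.na(flank_raw) | nchar(flank_raw) != 15L |
       !grepl("^_*[A-Z]+_*$", flank_raw))
  keep_grammar <- !(bad_site | bad_residue | bad_flank)

  tally <- c(
    malformed_site = sum(bad_site),
    non_sty_residue = sum(bad_residue),
    invalid_flank = sum(bad_flank)
  )
  tally <- tally[tally > 0]

  out <- tibble::tibble(
    gene_symbol = trimws(tab[[columns[["gene"]]]]),
    protein_accession = trimws(tab[[columns[["accession"]]]]),
    organism = tolower(trimws(tab[[columns[["organism"]]]])),
    residue = residue,
    position = position,
    flank_peptide = flank_raw,
    antibody_ids = split_antibody_ids(tab[[columns[["antibody"]]]]),
    site_label = site_label
  )[keep_grammar, ]
  out$center_matches <- substr(out$flank_peptide, 8L, 8L) == out$residue

  if (!is.null(organisms)) {
    out <- out[out$organism %in% tolower(organisms), ]
  }
  if (isTRUE(require_antibody)) {
    out <- out[lengths(out$antibody_ids) > 0, ]
  }
  if (sum(tally) > 0) {
    inform(paste0("skipped ", sum(tally), " malformed catalog row(s): ",
                  paste(names(tally), tally, sep = "=", collapse = " ")))
  }
  attr(out, "skip_tally") <- tally
  out
}

# Antibody cells hold one or more catalog numbers separated by ';' or ','.
split_antibody_ids <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    ids <- trimws(strsplit(cell, "[;,]")[[1]])
    ids[nzchar(ids)]
  })
}

#' Write a phosphosite catalog
#'
#' Serialises records produced by [read_phosphosite_catalog()] back to the
#' same tab-separated dialect (modified residue as `<AA><pos>-p`, the
#' flanking-peptide centre lowercased, antibody ids joined with `"; "`).
#' Parsing a written file recovers the records exactly.
#'
#' @param records Tibble from [read_phosphosite_catalog()].
#' @param path Output path.
#' @param preamble Optional character vector written verbatim before the
#'   header (mimicking release banners).
#' @export
write_phosphosite_catalog <- function(records, path, preamble = NULL) {
  flank <- paste0(
    substr(records$flank_peptide, 1, 7),
    tolower(substr(records$flank_peptide, 8, 8)),
    substr(records$flank_peptide, 9, 15)
  )
  tab <- tibble::tibble(
    GENE = records$gene_symbol,
    ACC_ID = records$protein_accession,
    ORGANISM = records$organism,
    MOD_RSD = records$site_label,
    `SITE_+/-7_AA` = flank,
    `CST_CAT#` = vapply(records$antibody_ids, paste, "", collapse = "; ")
  )
  body <- readr::format_tsv(tab)
  readr::write_lines(c(preamble, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Reads protein sequences (gzip accepted), taking the accession from the
#' first whitespace-delimited token of each header. Sequences are uppercased
#' and a trailing `*` stop character is stripped. Gap characters (`-`, `_`)
#' inside a sequence are a format error: they are alignment/padding symbols,
#' not residues.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `sequence`, in file order.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("[-_]", seqs))) {
    bad <- names(set)[grepl("[-_]", seqs)][1]
    abort(paste0("sequence contains gap/padding characters: ", bad))
  }
  if (any(!grepl("^[A-Z]*$", seqs))) {
    bad <- names(set)[!grepl("^[A-Z]*$", seqs)][1]
    abort(paste0("sequence contains non-residue characters: ", bad))
  }
  tibble::tibble(
    accession = vapply(strsplit(names(set), "\\s+"), `[`, "", 1),
    sequence = unname(seqs)
  )
}

#' Write a protein FASTA file
#'
#' @param proteins Tibble with `accession` and `sequence` columns.
#' @param path Output path.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$accession))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a ranked ortholog-pair table
#'
#' Reads a tab-separated table of source-gene/target-gene pairs with a
#' confidence rank (`high` > `moderate` > `low`), as exported by
#' DIOPT-style ortholog resources, and drops pairs below `min_rank`.
#'
#' @param path Path to the table (columns: source gene id, target gene id,
#'   rank; extra columns ignored). A header row is expected.
#' @param min_rank Minimum rank to keep: `"high"`, `"moderate"` (default) or
#'   `"low"`.
#' @return Tibble with columns `source_gene_id`, `target_gene_id`, `rank`
#'   (ordered factor low < moderate < high).
#' @export
read_ortholog_pairs <- function(path, min_rank = "moderate") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 3) {
    abort("ortholog table needs at least 3 columns: source gene, target gene, rank")
  }
  out <- tibble::tibble(
    source_gene_id = trimws(tab[[1]]),
    target_gene_id = trimws(tab[[2]]),
    rank = tolower(trimws(tab[[3]]))
  )
  bad <- which(!out$rank %in% c("high", "moderate", "low"))
  if (length(bad) > 0) {
    abort(paste0("unknown ortholog rank `", out$rank[bad[1]],
                 "` at table row ", bad[1]))
  }
  out$rank <- factor(out$rank, levels = c("low", "moderate", "high"),
                     ordered = TRUE)
  filter_rank(out, min_rank)
}

filter_rank <- function(pairs, min_rank) {
  min_rank <- match.arg(min_rank, c("high", "moderate", "low"))
  pairs[pairs$rank >= min_rank, , drop = FALSE]
}

#' Read a gene-identifier mapping table
#'
#' Two-column tab-separated table mapping an alias (gene symbol or protein
#' accession) to a gene identifier. A header row is expected; extra columns
#' are ignored.
#'
#' @param path Path to the table.
#' @return Tibble with columns `alias`, `gene_id`.
#' @export
read_gene_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2) {
    abort("gene map needs 2 columns: alias, gene id")
  }
  tibble::tibble(alias = trimws(tab[[1]]), gene_id = trimws(tab[[2]]))
}

report_columns <- c(
  "source_organism", "source_gene", "source_accession", "site_label",
  "target_gene", "target_accession", "identity_run", "best_strict",
  "best_relaxed", paste0("qualifies_at_", 6:11), "provenance"
)

#' Write the per-site conservation report
#'
#' Tab-separated, one row per (site x target isoform), with a fixed column
#' order: source organism, source gene, source accession, site label, target
#' gene, target accession, contiguous-identity run length, best strict
#' window length, best relaxed window length, qualification flags at cutoffs
#' 6-11, and anchoring provenance.
#'
#' @param results Conservation results tibble (see [evaluate_conservation()]).
#' @param path Output path.
#' @export
write_report <- function(results, path) {
  missing <- setdiff(report_columns, names(results))
  if (length(missing) > 0) {
    abort(paste0("results are missing report column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_tsv(results[report_columns], path, progress = FALSE)
  invisible(path)
}

#' Read back a conservation report written by [write_report()]
#'
#' @param path Path to a report file.
#' @return Tibble with typed report columns.
#' @export
read_report <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      identity_run = readr::col_integer(),
      best_strict = readr::col_integer(),
      best_relaxed = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  ) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("qualifies_at_"), as.logical))
}
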