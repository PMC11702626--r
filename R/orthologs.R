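#' Build a gene index for one organism
#'
#' Combines a proteome with identifier-mapping tables into the lookup
#' structure used by anchoring, gene resolution and isoform selection:
#' an alias-to-gene map (gene symbols and protein accessions, matched
#' case-insensitively) and a gene-to-proteins map (every isoform of each
#' gene). Protein accessions from `proteins` are added as aliases of their
#' own gene automatically. An alias that maps to two distinct gene ids is
#' remembered as ambiguous and refuses to resolve rather than guessing.
#'
#' @param proteins Tibble with columns `accession`, `sequence`, `gene_id`
#'   (optionally `gene_symbol`).
#' @param alias_map Optional tibble with columns `alias`, `gene_id`
#'   (gene symbols and/or extra accessions).
#' @return An object of class `gene_index`.
#' @export
build_gene_index <- function(proteins, alias_map = NULL) {
  stopifnot(all(c("accession", "sequence", "gene_id") %in% names(proteins)))
  aliases <- tibble::tibble(
    alias = proteins$accession,
    gene_id = proteins$gene_id
  )
  if (!is.null(alias_map)) {
    aliases <- dplyr::bind_rows(
      aliases,
      tibble::tibble(alias = alias_map$alias, gene_id = alias_map$gene_id)
    )
  }
  aliases$alias <- tolower(aliases$alias)
  aliases <- dplyr::distinct(aliases)
  amb <- unique(aliases$alias[duplicated(aliases$alias)])
  uniq <- aliases[!aliases$alias %in% amb, ]
  alias_to_gene <- setNames(uniq$gene_id, uniq$alias)

  gene_to_proteins <- split(
    proteins[c("accession", "sequence", "gene_id")],
    proteins$gene_id
  )
  # invariant: every gene id reachable through an alias has an entry,
  # possibly with zero proteins
  for (g in setdiff(unique(aliases$gene_id), names(gene_to_proteins))) {
    gene_to_proteins[[g]] <- proteins[0, c("accession", "sequence", "gene_id")]
  }
  structure(
    list(
      alias_to_gene = alias_to_gene,
      ambiguous_aliases = amb,
      gene_to_proteins = gene_to_proteins,
      accession_to_row = setNames(seq_len(nrow(proteins)), proteins$accession),
      proteins = proteins
    ),
    class = "gene_index"
  )
}

# Protein record (list) for an accession, or NULL.
index_protein <- function(index, accession) {
  i <- match(accession, names(index$accession_to_row))
  if (is.na(i)) return(NULL)
  as.list(index$proteins[i, c("accession", "sequence", "gene_id")])
}

lookup_chr <- function(map, key) {
  i <- match(key, names(map))
  if (is.na(i)) NA_character_ else map[[i]]
}

# All proteins of the gene(s) an alias (symbol) maps to; empty tibble when
# the alias is unknown or ambiguous.
index_symbol_proteins <- function(index, symbol) {
  g <- lookup_chr(index$alias_to_gene, tolower(symbol))
  if (is.na(g)) return(index$proteins[0, c("accession", "sequence", "gene_id")])
  index$gene_to_proteins[[g]] %||%
    index$proteins[0, c("accession", "sequence", "gene_id")]
}

#' @export
print.gene_index <- function(x, ...) {
  cat("<gene_index>", length(x$gene_to_proteins), "genes,",
      nrow(x$proteins), "proteins,", length(x$alias_to_gene), "aliases\n")
  invisible(x)
}

#' Resolve catalog records to gene identifiers
#'
#' Adds a `source_gene_id` column: the protein accession is tried first,
#' then the gene symbol (both case-insensitive). Records that resolve
#' through neither are tagged `unresolved_gene`; an alias known to map to
#' two distinct gene ids is tagged `ambiguous_alias` rather than guessed.
#'
#' @param records Tibble with `protein_accession` and `gene_symbol`
#'   columns (typically anchored sites).
#' @param index A [build_gene_index()] object.
#' @return `records` plus columns `source_gene_id` and `resolve_status`
#'   (`"ok"`, `"unresolved_gene"`, `"ambiguous_alias"`).
#' @export
resolve_genes <- function(records, index) {
  stopifnot(inherits(index, "gene_index"))
  resolve_one <- function(accession, symbol) {
    for (alias in c(tolower(accession), tolower(symbol))) {
      if (alias %in% index$ambiguous_aliases) {
        return(c(NA_character_, "ambiguous_alias"))
      }
      g <- lookup_chr(index$alias_to_gene, alias)
      if (!is.na(g)) return(c(g, "ok"))
    }
    c(NA_character_, "unresolved_gene")
  }
  if (nrow(records) == 0L) {
    records$source_gene_id <- character()
    records$resolve_status <- character()
    return(records)
  }
  out <- mapply(resolve_one, records$protein_accession, records$gene_symbol)
  records$source_gene_id <- unname(out[1, ])
  records$resolve_status <- unname(out[2, ])
  records
}

#' Target-species orthologs of a gene
#'
#' @param gene_id Source gene identifier.
#' @param pairs Ortholog-pair tibble (see [read_ortholog_pairs()]).
#' @param min_rank Minimum confidence rank to keep (default `"moderate"`).
#' @return Sorted, deduplicated character vector of target gene ids
#'   (empty when no ortholog passes the rank filter).
#' @export
orthologs_of <- function(gene_id, pairs, min_rank = "moderate") {
  kept <- filter_rank(pairs, min_rank)
  sort(unique(kept$target_gene_id[kept$source_gene_id == gene_id]))
}

#' Expand resolved sites to their ortholog set
#'
#' One output row per (site, target gene); one-to-many orthology is
#' preserved so every passing ortholog is evaluated. Optionally a paralog
#' pair table with identical semantics can widen the expansion.
#'
#' @param records Tibble with a `source_gene_id` column ([resolve_genes()]).
#' @param pairs Ortholog-pair tibble.
#' @param min_rank Minimum confidence rank.
#' @param paralog_pairs Optional second pair table (e.g. within-species
#'   paralogs), off by default.
#' @return `records` joined to passing pairs, with a `target_gene_id`
#'   column; rows without any passing ortholog are dropped (count them via
#'   the `n_unmapped` attribute).
#' @export
expand_orthologs <- function(records, pairs, min_rank = "moderate",
                             paralog_pairs = NULL) {
  kept <- filter_rank(pairs, min_rank)
  if (!is.null(paralog_pairs)) {
    kept <- dplyr::bind_rows(kept, filter_rank(paralog_pairs, min_rank))
  }
  kept <- dplyr::distinct(kept[c("source_gene_id", "target_gene_id")])
  out <- dplyr::inner_join(records, kept, by = "source_gene_id",
                           relationship = "many-to-many")
  out <- dplyr::arrange(out, dplyr::pick(dplyr::any_of(
    c("source_gene_id", "site_label", "target_gene_id")
  )))
  attr(out, "n_unmapped") <-
    length(setdiff(unique(records$source_gene_id), kept$source_gene_id))
  out
}

#' Select protein isoforms of a gene
#'
#' `mode = "all"` returns every isoform (used for alignment: an antibody may
#' cross-react with any isoform carrying the conserved window, which also
#' predicts multiple bands on a blot); `mode = "longest"` returns the single
#' longest isoform (ties broken by lexicographic accession), the convention
#' used for per-gene summaries.
#'
#' @param gene_id Gene identifier.
#' @param index A [build_gene_index()] object.
#' @param mode `"all"` or `"longest"`.
#' @return Tibble of proteins (possibly empty).
#' @export
select_isoforms <- function(gene_id, index, mode = c("all", "longest")) {
  mode <- match.arg(mode)
  prots <- index$gene_to_proteins[[gene_id]] %||%
    index$proteins[0, c("accession", "sequence", "gene_id")]
  if (mode == "longest" && nrow(prots) > 0) {
    prots <- prots[order(-nchar(prots$sequence), prots$accession)[1], ]
  }
  prots
}
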