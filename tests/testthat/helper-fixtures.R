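# In-code fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

catalog_fixture_lines <- function() {
  c(
    "Phosphosite catalog",
    "synthetic release banner",
    "",
    paste("GENE", "ACC_ID", "ORGANISM", "MOD_RSD", "SITE_+/-7_AA", "CST_CAT#",
          sep = "\t"),
    paste("AKT1", "P31749", "human", "S473-p", "RPHFPQFsYSASGTA", "#9271",
          sep = "\t"),
    paste("RPS6KB1", "P23443", "human", "T389-p", "NQVFLGFtYVAPSVL", "#9205; #9206",
          sep = "\t"),
    paste("UBB", "P0CG47", "human", "K48-ub", "LRLRGGAkQLEDGRT", "#4289",
          sep = "\t"),
    paste("AKT1", "F1NGG5", "chicken", "S473-p", "RPHFPQFsYSASGTA", "#9271",
          sep = "\t"),
    paste("BAD1", "Q00001", "human", "S99-p", "SHORT", "#1",
          sep = "\t"),
    paste("NOAB", "Q00002", "human", "S10-p", "AAAAAAAsAAAAAAA", "",
          sep = "\t"),
    paste("DRIFT", "Q00003", "human", "S20-p", "AAAAAAAtAAAAAAA", "#2",
          sep = "\t")
  )
}

catalog_fixture_file <- function() {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(catalog_fixture_lines(), f)
  f
}

# A minimal source-species index: two genes, one with two isoforms.
tiny_index <- function() {
  build_gene_index(
    tibble::tibble(
      accession = c("SP1.1", "SP2.1", "SP2.2"),
      sequence = c(
        paste0("MAA", "RPHFPQFSYSASGTA", "KLMNPQ"),
        paste0("MKVSYTTPGGT", "WDEF"),
        paste0("MKVSYTTPGGT", "WDEFGHIKLMN")
      ),
      gene_id = c("G1", "G2", "G2")
    ),
    alias_map = tibble::tibble(
      alias = c("akt1", "gene2"),
      gene_id = c("G1", "G2")
    )
  )
}

site_record <- function(gene_symbol = "AKT1", protein_accession = "SP1.1",
                        organism = "human", residue = "S", position = 11L,
                        flank_peptide = "RPHFPQFSYSASGTA",
                        site_label = NULL) {
  tibble::tibble(
    gene_symbol = gene_symbol,
    protein_accession = protein_accession,
    organism = organism,
    residue = residue,
    position = as.integer(position),
    flank_peptide = flank_peptide,
    antibody_ids = list("#1"),
    site_label = site_label %||% paste0(residue, position, "-p"),
    center_matches = substr(flank_peptide, 8, 8) == residue
  )
}
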