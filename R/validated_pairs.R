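#' Validated cross-reactive epitope pairs (human vs. fly)
#'
#' The curated set of 12 commercial phospho-antibody epitopes raised
#' against human proteins with reported cross-reactivity on the orthologous
#' *Drosophila melanogaster* protein: the +/-7 flanking peptide of the human
#' phosphosite, the aligned fly peptide, and the published length of the
#' conserved (contiguous identical) region through the site. These pairs
#' are the calibration set for the window-conservation rules: the smallest
#' conserved region among antibodies known to cross-react is 6 residues,
#' which motivates scanning window cutoffs 6-11.
#'
#' @return Tibble with columns `source_gene`, `target_gene`,
#'   `source_peptide`, `target_peptide` (both 15-mers, phosphosite at
#'   position 8), `reported_run`.
#' @examples
#' evaluate_peptide_pairs(validated_epitope_pairs())
#' @export
validated_epitope_pairs <- function() {
  tibble::tribble(
    ~source_gene, ~target_gene, ~source_peptide, ~target_peptide, ~reported_run,
    "AKT1",     "Akt1",      "RPHFPQFSYSASGTA", "EPLFPQFSYQGDMAS", 6L,
    "PRKAA1",   "AMPKalpha", "SDGEFLRTSCGSPNY", "LDGEFLRTSCGSPNY", 14L,
    "MAPK10",   "bsk",       "AGTSFMMTPYVVTRY", "AGTTFMMTPYVVTRY", 11L,
    "MAPK10",   "bsk",       "TSFMMTPYVVTRYYR", "TTFMMTPYVVTRYYR", 13L,
    "EIF2S1",   "eIF2alpha", "MILLSELSRRRIRSI", "MILLSELSRRRIRSI", 15L,
    "MAPK12",   "p38a",      "RQADSEMTGYVVTRW", "RPTENEMTGYVATRW", 6L,
    "MAPK12",   "p38a",      "ADSEMTGYVVTRWYR", "TENEMTGYVATRWYR", 6L,
    "MAPK1",    "rl",        "HDHTGFLTEYVATRW", "HDHTGFLTEYVATRW", 15L,
    "MAPK1",    "rl",        "HTGFLTEYVATRWYR", "HTGFLTEYVATRWYR", 15L,
    "RPS6KB1",  "S6k",       "NQVFLGFTYVAPSVL", "NLIFQGFTYVAPSIL", 8L,
    "EIF4EBP1", "Thor",      "PPGDYSTTPGGTLFS", "MPEVYSSTPGGTLYS", 6L,
    "EIF4EBP1", "Thor",      "GGTLFSTTPGGTRII", "GGTLYSTTPGGTKLI", 7L
  )
}
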