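test_that("unpad_flank strips terminus padding and tracks the site offset", {
  expect_equal(unpad_flank("RPHFPQFSYSASGTA"),
               list(core_peptide = "RPHFPQFSYSASGTA", core_site_offset = 7L))
  expect_equal(unpad_flank("____MKVSYTTPGGT"),
               list(core_peptide = "MKVSYTTPGGT", core_site_offset = 3L))
  expect_equal(unpad_flank("MILLSELSRRRIRS_"),
               list(core_peptide = "MILLSELSRRRIRS", core_site_offset = 7L))
  expect_error(unpad_flank("AAAA_AAASAAAAAA"), "padding")
  expect_error(unpad_flank("TOOSHORT"), "15")
})

test_that("anchor_direct trusts the peptide over the claimed coordinate", {
  seqn <- paste0("MAA", "RPHFPQFSYSASGTA", "KLMNPQ")  # core starts at 4

  hit <- anchor_direct(site_record(position = 11), seqn)
  expect_true(hit$ok)
  expect_equal(hit$position, 11L)
  expect_equal(hit$provenance, "direct")

  # stale coordinate, unique occurrence: the implied position wins
  shifted <- anchor_direct(site_record(position = 473), seqn)
  expect_true(shifted$ok)
  expect_equal(shifted$position, 11L)
  expect_equal(shifted$provenance, "position_shifted")

  miss <- anchor_direct(site_record(position = 11), "MKVLLSAAAA")
  expect_false(miss$ok)
  expect_equal(miss$reason, "peptide_not_found")
})

test_that("repeated peptides anchor only when the claim disambiguates", {
  core <- "RPHFPQFSYSASGTA"
  twice <- paste0("MAA", core, "GG", core, "WW")
  # occurrences at 4 and 21 -> implied sites 11 and 28

  expect_equal(anchor_direct(site_record(position = 100), twice)$reason,
               "ambiguous_peptide")
  picked <- anchor_direct(site_record(position = 28), twice)
  expect_true(picked$ok)
  expect_equal(picked$provenance, "direct")
  expect_equal(picked$position, 28L)
})

test_that("padded flanks anchor at protein termini", {
  rec <- site_record(protein_accession = "SP2.1", gene_symbol = "gene2",
                     residue = "S", position = 4,
                     flank_peptide = "____MKVSYTTPGGT")
  hit <- anchor_direct(rec, "MKVSYTTPGGTWDEF")
  expect_true(hit$ok)
  expect_equal(hit$position, 4L)
})

test_that("rescue_by_symbol picks the longest matching candidate", {
  core <- "RPHFPQFSYSASGTA"
  withr::with_seed(5, {
    long <- paste0(random_protein(240), core, random_protein(245))
    short <- paste0(random_protein(100), core, random_protein(185))
  })
  cands <- tibble::tibble(
    accession = c("NP_b", "NP_a"),
    sequence = c(short, long)
  )
  got <- rescue_by_symbol(site_record(position = 999), cands)
  expect_true(got$ok)
  expect_equal(got$accession, "NP_a")
  expect_equal(got$provenance, "rescued_by_symbol")
  expect_equal(substr(long, got$position, got$position), "S")

  # equal lengths: lexicographic accession breaks the tie
  tie <- tibble::tibble(accession = c("NP_z", "NP_a"),
                        sequence = c(long, long))
  expect_equal(rescue_by_symbol(site_record(), tie)$accession, "NP_a")

  none <- tibble::tibble(accession = "NP_x", sequence = random_protein(60))
  expect_equal(rescue_by_symbol(site_record(), none)$reason,
               "peptide_not_found")
  expect_equal(rescue_by_symbol(site_record(), none[0, ])$reason,
               "accession_not_found")

  dup <- tibble::tibble(accession = "NP_d",
                        sequence = paste0(core, "GGG", core))
  expect_equal(rescue_by_symbol(site_record(), dup)$reason,
               "ambiguous_peptide")
})

test_that("anchor_sites partitions records between anchors and tally", {
  idx <- tiny_index()
  records <- dplyr::bind_rows(
    site_record(),                                        # direct
    site_record(protein_accession = "GONE.1", gene_symbol = "AKT1",
                position = 11),                           # rescue via symbol
    site_record(gene_symbol = "AKT1", protein_accession = "NONE.1",
                flank_peptide = "WWWWWWWSWWWWWWW")        # peptide unmatched
  )
  anchored <- anchor_sites(records, idx)
  expect_equal(nrow(anchored), 2L)
  expect_equal(anchored$provenance, c("direct", "rescued_by_symbol"))
  tally <- attr(anchored, "skip_tally")
  expect_equal(sum(tally), 1L)
  expect_equal(unname(tally[["peptide_not_found"]]), 1L)
  expect_equal(nrow(anchored) + sum(tally), nrow(records))

  # degenerate inputs
  expect_equal(nrow(anchor_sites(records[0, ], idx)), 0L)
  dup <- anchor_sites(dplyr::bind_rows(site_record(), site_record()), idx)
  expect_equal(nrow(dup), 2L)
})

test_that("anchored sites reproduce the catalog flank, padding included", {
  idx <- tiny_index()
  withr::with_seed(31, {
    for (i in 1:60) {
      seqn <- random_protein(sample(30:90, 1))
      pos <- sample(nchar(seqn), 1)
      res <- sample(c("S", "T", "Y"), 1)
      substr(seqn, pos, pos) <- res
      flank <- flank_at(seqn, pos)
      rec <- site_record(protein_accession = "RT.1", gene_symbol = "rtgene",
                         residue = res, position = pos, flank_peptide = flank)
      one_idx <- build_gene_index(
        tibble::tibble(accession = "RT.1", sequence = seqn, gene_id = "GR"),
        tibble::tibble(alias = "rtgene", gene_id = "GR")
      )
      anc <- anchor_sites(rec, one_idx)
      if (nrow(anc) == 1L) {
        expect_equal(flank_at(seqn, anc$anchored_position), flank)
        expect_equal(substr(seqn, anc$anchored_position, anc$anchored_position),
                     rec$residue)
      } else {
        # only admissible failure on a planted site is peptide ambiguity
        expect_equal(attr(anc, "failures")$reason, "ambiguous_peptide")
      }
    }
  })
})

test_that("cores shorter than 4 residues are unanchorable", {
  rec <- site_record(flank_peptide = "______MSY______", residue = "S",
                     position = 2)
  expect_equal(anchor_direct(rec, "MSYLLK")$reason, "peptide_too_short")
})
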