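test_that("identity_run reproduces the validated epitope golden set", {
  pairs <- validated_epitope_pairs()
  runs <- purrr::map2_int(pairs$source_peptide, pairs$target_peptide,
                          identity_run, site_pos = 8)
  expect_equal(runs, pairs$reported_run)
  # and agrees with the position-by-position oracle
  oracle <- purrr::map2_int(pairs$source_peptide, pairs$target_peptide,
                            oracle_identity_run, site = 8)
  expect_equal(runs, oracle)
})

test_that("identity_run is zero iff the site differs, symmetric, maximal on self", {
  expect_equal(identity_run("AAAA", "CCCC", 2), 0L)
  withr::with_seed(41, {
    for (i in 1:40) {
      w <- random_protein(15)
      v <- random_protein(15)
      s <- sample(15, 1)
      expect_equal(identity_run(w, w, s), 15L)
      expect_equal(identity_run(w, v, s), identity_run(v, w, s))
      expect_equal(identity_run(w, v, s), oracle_identity_run(w, v, s))
      if (substr(w, s, s) != substr(v, s, s)) {
        expect_equal(identity_run(w, v, s), 0L)
      } else {
        expect_gte(identity_run(w, v, s), 1L)
      }
    }
  })
  expect_error(identity_run("AAA", "AAAA", 1), "equal length")
  expect_error(identity_run("A-A", "AAA", 1), "gap-free")
})

test_that("window qualification enforces the single-distant-substitution rule", {
  sg <- similarity_groups()
  expect_true(window_qualifies("ABCDEFGH", "ABCDEFGH", 5, sg))
  # one conservative pair (I<->L) at distance 3 from the site
  expect_true(window_qualifies("AICDEFGH", "ALCDEFGH", 5, sg))
  expect_false(window_qualifies("AICDEFGH", "ALCDEFGH", 5, sg,
                                allow_conservative = FALSE))
  # adjacent to the site: refused
  expect_false(window_qualifies("ABCDIFGH", "ABCDLFGH", 4, sg))
  # at the site: refused
  expect_false(window_qualifies("ABCSEFGH", "ABCTEFGH", 4, sg))
  # two conservative substitutions: refused
  expect_false(window_qualifies("AICDEFGH", "ALCDEFGG", 5, sg))
  # one non-conservative mismatch: refused
  expect_false(window_qualifies("AWCDEFGH", "ADCDEFGH", 5, sg))
  # strict implies relaxed
  withr::with_seed(43, {
    for (i in 1:30) {
      a <- random_protein(9)
      b <- random_protein(9)
      s <- sample(9, 1)
      if (window_qualifies(a, b, s, sg, allow_conservative = FALSE)) {
        expect_true(window_qualifies(a, b, s, sg))
      }
    }
  })
})

test_that("similarity schemes are symmetric, irreflexive and configurable", {
  for (sg in list(similarity_groups(),
                  similarity_groups("blosum62_positive"))) {
    expect_false(any(is_conservative(sg, LETTERS, LETTERS)))
    for (p in list(c("I", "L"), c("D", "E"), c("S", "T"))) {
      expect_true(is_conservative(sg, p[1], p[2]))
      expect_equal(is_conservative(sg, p[1], p[2]),
                   is_conservative(sg, p[2], p[1]))
    }
    expect_false(is_conservative(sg, "W", "D"))
    expect_false(is_conservative(sg, "_", "A"))
  }
  expect_error(similarity_groups(groups = list(c("A", "B"), c("B", "C"))),
               "disjoint")
})

test_that("peptide pairs recover the printed window behaviour", {
  pairs <- validated_epitope_pairs()
  strict <- evaluate_peptide_pairs(pairs, allow_conservative = FALSE)

  thor <- strict[strict$source_peptide == "GGTLFSTTPGGTRII", ]
  expect_equal(thor$best_strict, 7L)
  expect_true(thor$qualifies_at_6)
  expect_true(thor$qualifies_at_7)
  expect_false(thor$qualifies_at_8)

  identical_rows <- strict[strict$source_peptide == strict$target_peptide, ]
  expect_equal(nrow(identical_rows), 3L)  # eIF2alpha + the two rl windows
  for (L in 6:11) {
    expect_true(all(identical_rows[[paste0("qualifies_at_", L)]]))
  }
})

test_that("best window lengths match exhaustive (start, length) enumeration", {
  sg <- similarity_groups()
  withr::with_seed(47, {
    for (i in 1:60) {
      src <- random_protein(15)
      tgt <- src
      # plant 0-3 mutations, some conservative
      for (k in seq_len(sample(0:3, 1))) {
        p <- sample(15, 1)
        res <- substr(src, p, p)
        repl <- if (runif(1) < 0.5) {
          partner <- crossphos:::CONS_PARTNER
          if (res %in% names(partner)) partner[[res]] else "P"
        } else "W"
        substr(tgt, p, p) <- repl
      }
      site <- sample(3:13, 1)
      for (allow in c(TRUE, FALSE)) {
        got <- evaluate_peptide_pairs(
          tibble::tibble(source_peptide = src, target_peptide = tgt),
          site_pos = site, allow_conservative = allow
        )
        want <- oracle_best_windows(src, tgt, site, 6:11, sg, allow)
        expect_equal(got$best_strict, want$best_strict,
                     info = paste(src, tgt, site))
        expect_equal(got$best_relaxed, want$best_relaxed,
                     info = paste(src, tgt, site, allow))
        # qualification flags are the monotone image of best_relaxed
        for (L in 6:11) {
          expect_equal(got[[paste0("qualifies_at_", L)]],
                       want$best_relaxed >= L)
        }
        if (got$identity_run <= 11) {
          expect_lte(got$best_strict, got$identity_run)
        }
      }
    }
  })
})

test_that("evaluate_site handles gaps, clipping and site-on-gap columns", {
  sg <- similarity_groups()

  # gapless identical proteins: everything qualifies, run capped by +/-7
  prot <- random_protein(60)
  ident <- align_global(prot, prot)
  ev <- evaluate_site(ident, 30)
  expect_equal(ev$identity_run, 15L)
  expect_equal(ev$best_strict, 11L)
  expect_true(all(unlist(ev[paste0("qualifies_at_", 6:11)])))

  # site near the N-terminus: windows clip to the sequence start
  ev_edge <- evaluate_site(ident, 2)
  expect_equal(ev_edge$best_strict, 11L)
  expect_equal(ev_edge$identity_run, 9L)  # 1 left + site + 7 right

  # site aligned to a target gap: all-false, zero run
  gap_site <- manual_alignment("ABCDEFGHIJKL", "ABCDE-GHIJKL")
  ev_gap <- evaluate_site(gap_site, 6)
  expect_equal(ev_gap$identity_run, 0L)
  expect_equal(ev_gap$best_relaxed, 0L)
  expect_false(any(unlist(ev_gap[paste0("qualifies_at_", 6:11)])))

  # a gap inside the neighbourhood truncates the run and blocks windows
  near_gap <- manual_alignment("ABCDEFGHIJKLMNOP", "ABC-EFGHIJKLMNOP")
  ev_near <- evaluate_site(near_gap, 8)
  expect_equal(ev_near$identity_run, 11L)  # truncated at the gap column
  expect_equal(ev_near$best_strict, 11L)   # windows right of the gap fit
  ev_tight <- evaluate_site(near_gap, 3)
  expect_equal(ev_tight$best_strict, 0L)   # every window crosses the gap
  expect_equal(ev_tight$identity_run, 3L)  # A..C, truncated rightwards
})

test_that("evaluate_site agrees with the peptide-only path on gapless pairs", {
  sg <- similarity_groups()
  withr::with_seed(53, {
    for (i in 1:12) {
      src <- random_protein(40)
      tgt <- src
      for (p in sample(40, sample(2:5, 1))) {
        substr(tgt, p, p) <- sample(c("P", "W", "L"), 1)
      }
      aln <- align_global(src, tgt)
      if (grepl("-", aln$aligned_source, fixed = TRUE) ||
          grepl("-", aln$aligned_target, fixed = TRUE)) next
      site <- sample(10:30, 1)
      full <- evaluate_site(aln, site)
      pep <- evaluate_peptide_pairs(
        tibble::tibble(source_peptide = src, target_peptide = tgt),
        site_pos = site
      )
      expect_equal(full$best_strict, pep$best_strict)
      expect_equal(full$best_relaxed, pep$best_relaxed)
    }
  })
})

test_that("summaries count sites and genes per cutoff, monotonically", {
  mk <- function(site, tgene, relaxed) {
    tibble::tibble(
      source_organism = "human", source_gene = sub("-.*", "", site),
      source_accession = "ACC", site_label = site,
      target_gene = tgene, target_accession = paste0(tgene, ".1"),
      identity_run = relaxed, best_strict = relaxed, best_relaxed = relaxed,
      !!!setNames(as.list(relaxed >= 6:11), paste0("qualifies_at_", 6:11)),
      provenance = "direct"
    )
  }
  res <- dplyr::bind_rows(
    mk("A-S5-p", "tg1", 6), mk("B-S9-p", "tg1", 6), mk("C-T3-p", "tg2", 11)
  )
  sm <- summarize_conservation(res)
  expect_equal(sm$n_sites[sm$cutoff == 6], 3L)
  expect_equal(sm$n_target_genes[sm$cutoff == 6], 2L)
  expect_equal(sm$n_sites[sm$cutoff == 11], 1L)
  expect_equal(sm$n_target_genes[sm$cutoff == 11], 1L)
  expect_true(all(diff(sm$n_sites) <= 0))
  expect_true(all(diff(sm$n_target_genes) <= 0))

  empty <- summarize_conservation(res[0, ])
  expect_true(all(empty$n_sites == 0L))

  # isoforms collapse to one site/gene
  iso <- dplyr::bind_rows(mk("A-S5-p", "tg1", 8), mk("A-S5-p", "tg1", 8))
  iso$target_accession <- c("tg1.1", "tg1.2")
  expect_equal(summarize_conservation(iso)$n_sites[1], 1L)
})
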