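test_that("identical sequences align gaplessly at the diagonal score", {
  toy <- scoring_scheme(toy_matrix(match = 1, mismatch = -1),
                        gap_open = -2, gap_extend = -2)
  aln <- align_global("AAAA", "AAAA", toy)
  expect_equal(aln$score, 4)
  expect_equal(aln$aligned_source, "AAAA")
  expect_equal(aln$aligned_target, "AAAA")

  b62 <- scoring_scheme()
  pep <- "HDHTGFLTEYVATRW"
  self <- align_global(pep, pep, b62)
  expect_equal(self$aligned_source, pep)
  expect_equal(self$aligned_target, pep)
  chars <- strsplit(pep, "")[[1]]
  expect_equal(self$score, sum(b62$matrix[cbind(chars, chars)]))
})

test_that("alignment invariants hold on random sequence pairs", {
  scheme <- scoring_scheme()
  withr::with_seed(101, {
    for (i in 1:25) {
      a <- random_protein(sample(5:60, 1))
      b <- random_protein(sample(5:60, 1))
      aln <- align_global(a, b, scheme)
      # equal-length rows, no all-gap column, ungapping restores inputs
      expect_equal(nchar(aln$aligned_source), nchar(aln$aligned_target))
      expect_equal(gsub("-", "", aln$aligned_source), a)
      expect_equal(gsub("-", "", aln$aligned_target), b)
      cols <- cbind(strsplit(aln$aligned_source, "")[[1]],
                    strsplit(aln$aligned_target, "")[[1]])
      expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
      # symmetric matrix => symmetric score
      expect_equal(align_global(b, a, scheme)$score, aln$score)
      # self-alignment is gapless
      self <- align_global(a, a, scheme)
      expect_equal(self$aligned_source, a)
      expect_equal(self$aligned_target, a)
    }
  })
})

test_that("scores match the exhaustive enumeration oracle on short pairs", {
  mat <- toy_matrix()
  scheme <- scoring_scheme(mat, gap_open = -3, gap_extend = -1)
  withr::with_seed(7, {
    for (i in 1:150) {
      a <- paste(sample(rownames(mat), sample(1:5, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(rownames(mat), sample(1:5, 1), replace = TRUE),
                 collapse = "")
      expect_equal(align_global(a, b, scheme)$score,
                   oracle_align_score(a, b, mat, -3, -1),
                   info = paste(a, b))
    }
  })
})

test_that("scores agree with an independent aligner under matched gap costs", {
  # Biostrings charges opening + extension on a gap's first column; this
  # package charges gap_open on the first column and gap_extend afterwards,
  # so gap_open = -(opening + extension) matches the two conventions.
  scheme <- scoring_scheme("BLOSUM62", gap_open = -10.5, gap_extend = -0.5)
  b62 <- crossphos:::substitution_matrix("BLOSUM62")
  withr::with_seed(13, {
    for (i in 1:10) {
      a <- random_protein(sample(10:80, 1))
      b <- random_protein(sample(10:80, 1))
      ref <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = b62, gapOpening = 10, gapExtension = 0.5,
        type = "global"
      )
      expect_equal(align_global(a, b, scheme)$score, Biostrings::score(ref))
    }
  })
})

test_that("unknown residues score at the matrix floor instead of failing", {
  mat <- toy_matrix()
  scheme <- scoring_scheme(mat, gap_open = -10, gap_extend = -1)
  aln <- align_global("AUA", "AUA", scheme)   # U absent from the toy matrix
  expect_equal(aln$score, 2 + 2 + min(mat))
})

test_that("empty or gapped sequences are rejected up front", {
  expect_error(align_global("", "ACD"), "non-empty")
  expect_error(align_global("AC-D", "ACD"), "residues")
})

test_that("position projection follows alignment columns", {
  ident <- align_global("HDHTGFLTEYVATRW", "HDHTGFLTEYVATRW")
  expect_equal(project_position(ident, 8),
               list(target_pos = 8L, column_index = 8L))

  ins <- manual_alignment("AB-C", "ABDC")
  expect_equal(project_position(ins, 3),
               list(target_pos = 4L, column_index = 4L))

  del <- manual_alignment("ABC", "A-C")
  expect_equal(project_position(del, 2)$target_pos, NA_integer_)
  expect_error(project_position(del, 9), "outside")
})

test_that("projection is strictly increasing over residue-mapped positions", {
  withr::with_seed(23, {
    for (i in 1:8) {
      a <- random_protein(40)
      b <- random_protein(sample(25:55, 1))
      aln <- align_global(a, b)
      tp <- vapply(seq_len(nchar(a)),
                   function(p) project_position(aln, p)$target_pos %||% NA_integer_,
                   NA_integer_)
      mapped <- tp[!is.na(tp)]
      expect_true(all(diff(mapped) > 0))
    }
  })
})

test_that("aligned windows carry their gap status", {
  ident <- align_global("HDHTGFLTEYVATRW", "HDHTGFLTEYVATRW")
  w <- extract_aligned_window(ident, 3, 6)
  expect_equal(w$source_window, w$target_window)
  expect_false(w$has_gap)

  gapped <- manual_alignment("ABCD-EF", "AB-DXEF")
  w2 <- extract_aligned_window(gapped, 2, 3)   # spans the C/- column
  expect_true(w2$has_gap)
  w3 <- extract_aligned_window(gapped, 1, 1)
  expect_equal(w3$source_window, "A")
  expect_false(w3$has_gap)
  # source window 4..5 spans the target-insertion column
  w4 <- extract_aligned_window(gapped, 4, 2)
  expect_equal(w4$source_window, "D-E")
  expect_true(w4$has_gap)
  expect_error(extract_aligned_window(gapped, 4, 9), "outside")
})

test_that("tidy and glance expose per-column and whole-alignment views", {
  aln <- align_global("HEAGAWGHEE", "PAWHEAE")
  td <- tidy(aln)
  expect_equal(nrow(td), nchar(aln$aligned_source))
  expect_equal(max(td$source_pos, na.rm = TRUE), 10L)
  expect_equal(max(td$target_pos, na.rm = TRUE), 7L)
  gl <- glance(aln)
  expect_equal(gl$score, aln$score)
  expect_true(gl$identity >= 0 && gl$identity <= 1)
})
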