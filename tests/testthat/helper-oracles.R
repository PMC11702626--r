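# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle enumerates every global
# alignment as a lattice path; the window oracle re-derives the
# conservation rules with plain positional comparisons.

# All monotone lattice paths from (0,0) to (n,m); moves: 1 diagonal,
# 2 down (source residue over a gap), 3 right (gap over target residue).
paths_for_shape <- local({
  cache <- new.env(parent = emptyenv())
  function(n, m) {
    key <- paste(n, m)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    res <- list()
    rec <- function(i, j, moves) {
      if (i == n && j == m) {
        res[[length(res) + 1L]] <<- moves
        return(invisible())
      }
      if (i < n && j < m) rec(i + 1L, j + 1L, c(moves, 1L))
      if (i < n) rec(i + 1L, j, c(moves, 2L))
      if (j < m) rec(i, j + 1L, c(moves, 3L))
    }
    rec(0L, 0L, integer())
    cache[[key]] <- res
    res
  }
})

# Per-shape scoring tables: affine gap cost of every path (sequence
# independent) plus the (source, target) coordinates of each diagonal move,
# flattened with a path id so substitution scores aggregate with rowsum().
shape_tables <- local({
  cache <- new.env(parent = emptyenv())
  function(n, m, gap_open, gap_extend) {
    key <- paste(n, m, gap_open, gap_extend)
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    paths <- paths_for_shape(n, m)
    gap <- vapply(paths, function(mv) {
      r <- rle(mv)
      keep <- r$values != 1L
      sum(gap_open + (r$lengths[keep] - 1L) * gap_extend)
    }, numeric(1))
    di <- list(); dj <- list(); pid <- list()
    for (p in seq_along(paths)) {
      mv <- paths[[p]]
      ii <- cumsum(mv != 3L)
      jj <- cumsum(mv != 2L)
      d <- mv == 1L
      di[[p]] <- ii[d]
      dj[[p]] <- jj[d]
      pid[[p]] <- rep(p, sum(d))
    }
    out <- list(gap = gap, di = unlist(di), dj = unlist(dj),
                pid = unlist(pid), n_paths = length(paths))
    cache[[key]] <- out
    out
  }
})

# Exhaustive optimal global alignment score: max over every alignment.
oracle_align_score <- function(a, b, mat, gap_open, gap_extend) {
  ai <- match(strsplit(a, "")[[1]], rownames(mat))
  bi <- match(strsplit(b, "")[[1]], colnames(mat))
  st <- shape_tables(nchar(a), nchar(b), gap_open, gap_extend)
  sums <- numeric(st$n_paths)
  if (length(st$di) > 0) {
    v <- mat[cbind(ai[st$di], bi[st$dj])]
    agg <- rowsum(v, st$pid)
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  max(st$gap + sums)
}

# Direct re-derivation of the window-conservation rules over every
# (start, length) placement on a pre-aligned gap-free pair.
oracle_best_windows <- function(src, tgt, site, cutoffs = 6:11,
                                groups = similarity_groups(),
                                allow_conservative = TRUE) {
  sc <- strsplit(src, "")[[1]]
  tc <- strsplit(tgt, "")[[1]]
  n <- length(sc)
  best_strict <- 0L
  best_relaxed <- 0L
  for (L in cutoffs) {
    for (s in seq_len(n - L + 1L)) {
      idx <- s:(s + L - 1L)
      if (!(site %in% idx)) next
      mis <- idx[sc[idx] != tc[idx]]
      if (length(mis) == 0L) {
        best_strict <- max(best_strict, L)
        best_relaxed <- max(best_relaxed, L)
      } else if (allow_conservative && length(mis) == 1L &&
                 abs(mis - site) >= 2L &&
                 is_conservative(groups, sc[mis], tc[mis])) {
        best_relaxed <- max(best_relaxed, L)
      }
    }
  }
  list(best_strict = best_strict,
       best_relaxed = max(best_relaxed, best_strict))
}

# Center-anchored contiguous identity run, written position-by-position.
oracle_identity_run <- function(src, tgt, site) {
  sc <- strsplit(src, "")[[1]]
  tc <- strsplit(tgt, "")[[1]]
  if (sc[site] != tc[site]) return(0L)
  run <- 1L
  k <- site - 1L
  while (k >= 1L && sc[k] == tc[k]) {
    run <- run + 1L
    k <- k - 1L
  }
  k <- site + 1L
  while (k <= length(sc) && sc[k] == tc[k]) {
    run <- run + 1L
    k <- k + 1L
  }
  run
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# A small substitution matrix over a 4-letter alphabet for oracle tests.
toy_matrix <- function(match = 2, mismatch = -1,
                       alphabet = c("A", "C", "G", "T")) {
  k <- length(alphabet)
  m <- matrix(mismatch, k, k, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# Hand-built alignment object for exercising projection helpers without
# going through the aligner.
manual_alignment <- function(src_row, tgt_row, score = 0) {
  structure(
    list(aligned_source = src_row, aligned_target = tgt_row, score = score,
         source_accession = "src", target_accession = "tgt",
         scheme_name = "manual"),
    class = "protein_alignment"
  )
}
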