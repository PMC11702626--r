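#' Contiguous-identity run through a site
#'
#' Length of the longest run of positions at which two equal-length,
#' gap-free windows are identical, where the run must contain the site
#' position. Returns 0 exactly when the two windows differ at the site
#' itself; otherwise at least 1. This is the "conserved region (contiguous
#' residues)" statistic reported for validated cross-reactive epitopes.
#'
#' @param source_window,target_window Equal-length gap-free residue strings.
#' @param site_pos 1-based position of the phosphosite within the windows
#'   (the centre of a 15-mer is position 8).
#' @return Integer run length.
#' @examples
#' identity_run("RPHFPQFSYSASGTA", "EPLFPQFSYQGDMAS", 8)
#' @export
identity_run <- function(source_window, target_window, site_pos) {
  a <- check_window_pair(source_window, target_window, site_pos)
  eq <- a$src == a$tgt
  if (!eq[site_pos]) return(0L)
  lo <- site_pos
  while (lo > 1L && eq[lo - 1L]) lo <- lo - 1L
  hi <- site_pos
  while (hi < length(eq) && eq[hi + 1L]) hi <- hi + 1L
  as.integer(hi - lo + 1L)
}

check_window_pair <- function(source_window, target_window, site_pos) {
  if (nchar(source_window) != nchar(target_window)) {
    abort("windows must have equal length")
  }
  if (grepl("-", source_window, fixed = TRUE) ||
      grepl("-", target_window, fixed = TRUE)) {
    abort("windows must be gap-free")
  }
  if (site_pos < 1L || site_pos > nchar(source_window)) {
    abort("`site_pos` is outside the window")
  }
  list(
    src = strsplit(source_window, "", fixed = TRUE)[[1]],
    tgt = strsplit(target_window, "", fixed = TRUE)[[1]]
  )
}

#' Does a window qualify as conserved?
#'
#' A window qualifies when every position is identical between source and
#' target -- except that, when `allow_conservative` is `TRUE`, at most one
#' position may instead carry a conservative substitution (per `groups`),
#' and that position must not be the phosphosite nor immediately adjacent
#' to it (`|pos - site_pos| >= 2`). The phosphosite itself must always
#' match: it is the residue the antibody's phospho-specificity reads.
#'
#' @inheritParams identity_run
#' @param groups A [similarity_groups()] object.
#' @param allow_conservative Permit the single-substitution relaxation.
#' @return Logical.
#' @export
window_qualifies <- function(source_window, target_window, site_pos,
                             groups = similarity_groups(),
                             allow_conservative = TRUE) {
  a <- check_window_pair(source_window, target_window, site_pos)
  mis <- which(a$src != a$tgt)
  if (length(mis) == 0L) return(TRUE)
  if (!allow_conservative || length(mis) > 1L) return(FALSE)
  abs(mis - site_pos) >= 2L &&
    is_conservative(groups, a$src[mis], a$tgt[mis])
}

# Best qualifying window lengths over a pre-aligned, gap-free pair of
# equal-length strings: enumerate every (start, L) window containing the
# site for each cutoff L.
best_window_lengths <- function(src, tgt, site_pos, cutoffs = 6:11,
                                groups = similarity_groups(),
                                allow_conservative = TRUE) {
  n <- nchar(src)
  best_strict <- 0L
  best_relaxed <- 0L
  for (L in sort(unique(as.integer(cutoffs)))) {
    starts <- seq.int(max(1L, site_pos - L + 1L), min(site_pos, n - L + 1L))
    if (length(starts) == 0L || starts[1] > min(site_pos, n - L + 1L)) next
    for (s in starts) {
      sw <- substr(src, s, s + L - 1L)
      tw <- substr(tgt, s, s + L - 1L)
      sp <- site_pos - s + 1L
      if (best_strict < L &&
          window_qualifies(sw, tw, sp, groups, allow_conservative = FALSE)) {
        best_strict <- L
      }
      if (best_relaxed < L &&
          window_qualifies(sw, tw, sp, groups,
                           allow_conservative = allow_conservative)) {
        best_relaxed <- L
      }
      if (best_strict == L && best_relaxed == L) break
    }
  }
  list(best_strict = best_strict, best_relaxed = max(best_relaxed, best_strict))
}

qualifies_cols <- function(best_relaxed, cutoffs = 6:11) {
  setNames(
    as.list(best_relaxed >= cutoffs),
    paste0("qualifies_at_", cutoffs)
  )
}

#' Score conservation of one anchored site on one aligned target
#'
#' The core per-(site x isoform) statistic. For each cutoff `L` in
#' `cutoffs`, every contiguous source window of length `L` containing the
#' anchored position (clipped to the sequence bounds) is projected through
#' the alignment; windows touching any gap column in either row are
#' disqualified (an epitope is a contiguous peptide -- a gap breaks it),
#' the remainder are tested with [window_qualifies()]. `best_strict` /
#' `best_relaxed` are the largest qualifying cutoffs under strict identity
#' and under the one-conservative-substitution relaxation;
#' `qualifies_at_L` is `best_relaxed >= L`. The contiguous-identity run is
#' computed over the +/-7 aligned neighbourhood of the site, truncated at
#' the first gap column on either side.
#'
#' A site whose residue is aligned to a gap in the target yields an
#' all-false result with `identity_run = 0`.
#'
#' @param aln A `protein_alignment` whose source row carries the site.
#' @param anchored_position 1-based site position on the ungapped source.
#' @param cutoffs Integer window lengths to test (default 6:11).
#' @inheritParams window_qualifies
#' @return One-row tibble: `identity_run`, `best_strict`, `best_relaxed`,
#'   `qualifies_at_<L>` for each cutoff.
#' @export
evaluate_site <- function(aln, anchored_position, cutoffs = 6:11,
                          groups = similarity_groups(),
                          allow_conservative = TRUE) {
  cutoffs <- sort(unique(as.integer(cutoffs)))
  cols <- alignment_columns(aln)
  n_src <- max(cols$source_pos)
  site <- as.integer(anchored_position)
  if (site < 1L || site > n_src) {
    abort("`anchored_position` is outside the ungapped source sequence")
  }
  site_col <- which(cols$source != "-" & cols$source_pos == site)

  zero <- tibble::tibble(
    identity_run = 0L, best_strict = 0L, best_relaxed = 0L,
    !!!qualifies_cols(0L, cutoffs)
  )
  if (cols$target[site_col] == "-") {
    return(zero)
  }

  gap_col <- cols$source == "-" | cols$target == "-"

  best_strict <- 0L
  best_relaxed <- 0L
  for (L in cutoffs) {
    lo_start <- max(1L, site - L + 1L)
    hi_start <- min(site, n_src - L + 1L)
    if (lo_start > hi_start) next
    for (s in lo_start:hi_start) {
      first <- which(cols$source != "-" & cols$source_pos == s)
      last <- which(cols$source != "-" & cols$source_pos == s + L - 1L)
      span <- first:last
      if (any(gap_col[span])) next
      sw <- paste(cols$source[span], collapse = "")
      tw <- paste(cols$target[span], collapse = "")
      sp <- site - s + 1L
      if (best_strict < L &&
          window_qualifies(sw, tw, sp, groups, allow_conservative = FALSE)) {
        best_strict <- L
      }
      if (best_relaxed < L &&
          window_qualifies(sw, tw, sp, groups,
                           allow_conservative = allow_conservative)) {
        best_relaxed <- L
      }
      if (best_strict == L && best_relaxed == L) break
    }
  }
  best_relaxed <- max(best_relaxed, best_strict)

  # +/-7 aligned neighbourhood, truncated at the first gap column
  left <- 0L
  while (left < 7L && site_col - left - 1L >= 1L &&
         !gap_col[site_col - left - 1L]) {
    left <- left + 1L
  }
  right <- 0L
  while (right < 7L && site_col + right + 1L <= length(gap_col) &&
         !gap_col[site_col + right + 1L]) {
    right <- right + 1L
  }
  span <- (site_col - left):(site_col + right)
  run <- identity_run(
    paste(cols$source[span], collapse = ""),
    paste(cols$target[span], collapse = ""),
    left + 1L
  )

  tibble::tibble(
    identity_run = run, best_strict = best_strict,
    best_relaxed = best_relaxed,
    !!!qualifies_cols(best_relaxed, cutoffs)
  )
}

#' Evaluate conservation for every (site, target gene) pair
#'
#' Aligns each anchored source protein against every selected isoform of
#' each mapped target gene and scores the site with [evaluate_site()].
#' Alignments are cached per protein pair, so many sites on one protein
#' cost a single alignment per target isoform.
#'
#' @param mapped Tibble of anchored, gene-resolved, ortholog-expanded sites
#'   (from [anchor_sites()] + [resolve_genes()] + [expand_orthologs()]).
#' @param source_index,target_index [build_gene_index()] objects for the
#'   two species.
#' @param scheme A [scoring_scheme()].
#' @param isoforms `"all"` (default; every target isoform is scored) or
#'   `"longest"`.
#' @inheritParams evaluate_site
#' @return Results tibble, one row per (site x target isoform), holding the
#'   report columns (see [write_report()]) plus `source_gene_id` and
#'   `target_gene_id`.
#' @export
evaluate_conservation <- function(mapped, source_index, target_index,
                                  scheme = scoring_scheme(),
                                  cutoffs = 6:11,
                                  groups = similarity_groups(),
                                  allow_conservative = TRUE,
                                  isoforms = c("all", "longest")) {
  isoforms <- match.arg(isoforms)
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(mapped))) {
    rec <- mapped[i, ]
    src <- index_protein(source_index, rec$anchored_accession)
    if (is.null(src)) next
    targets <- select_isoforms(rec$target_gene_id, target_index, isoforms)
    for (j in seq_len(nrow(targets))) {
      key <- paste(rec$anchored_accession, targets$accession[j], sep = "\r")
      aln <- cache[[key]]
      if (is.null(aln)) {
        aln <- align_global(src$sequence, targets$sequence[j], scheme,
                            source_accession = src$accession,
                            target_accession = targets$accession[j])
        cache[[key]] <- aln
      }
      ev <- evaluate_site(aln, rec$anchored_position, cutoffs, groups,
                          allow_conservative)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          source_organism = rec$organism,
          source_gene = rec$gene_symbol,
          source_accession = rec$anchored_accession,
          site_label = rec$site_label,
          target_gene = rec$target_gene_id,
          target_accession = targets$accession[j],
          source_gene_id = rec$source_gene_id,
          target_gene_id = rec$target_gene_id,
          provenance = rec$provenance
        ),
        ev
      )
    }
  }
  if (length(rows) == 0L) {
    return(empty_results(cutoffs))
  }
  out <- dplyr::bind_rows(rows)
  out[c(setdiff(report_columns, "provenance"), "provenance",
        "source_gene_id", "target_gene_id")]
}

empty_results <- function(cutoffs = 6:11) {
  tibble::tibble(
    source_organism = character(), source_gene = character(),
    source_accession = character(), site_label = character(),
    target_gene = character(), target_accession = character(),
    identity_run = integer(), best_strict = integer(),
    best_relaxed = integer(),
    !!!setNames(rep(list(logical()), length(cutoffs)),
                paste0("qualifies_at_", cutoffs)),
    provenance = character(),
    source_gene_id = character(), target_gene_id = character()
  )
}

#' Summarise qualifying sites and genes per cutoff
#'
#' Counts, at each cutoff, the distinct catalog sites with at least one
#' qualifying (site x isoform) row, and the distinct source and target
#' genes carrying such a site -- isoforms collapse to genes. Counts are
#' monotone non-increasing in the cutoff.
#'
#' @param results Results tibble from [evaluate_conservation()] (or a
#'   re-read report).
#' @param cutoffs Cutoffs to summarise (default 6:11; each needs a
#'   `qualifies_at_<L>` column).
#' @return Tibble with columns `cutoff`, `n_sites`, `n_source_genes`,
#'   `n_target_genes`.
#' @export
summarize_conservation <- function(results, cutoffs = 6:11) {
  src_gene <- if ("source_gene_id" %in% names(results) &&
                  !all(is.na(results$source_gene_id)))
    results$source_gene_id else results$source_gene
  tgt_gene <- if ("target_gene_id" %in% names(results))
    results$target_gene_id else results$target_gene
  site_key <- paste(results$source_organism, src_gene, results$site_label,
                    sep = "\r")
  purrr::map_dfr(sort(unique(as.integer(cutoffs))), function(L) {
    col <- paste0("qualifies_at_", L)
    if (!col %in% names(results)) {
      abort(paste0("results lack column ", col))
    }
    q <- results[[col]]
    tibble::tibble(
      cutoff = L,
      n_sites = dplyr::n_distinct(site_key[q]),
      n_source_genes = dplyr::n_distinct(src_gene[q]),
      n_target_genes = dplyr::n_distinct(tgt_gene[q])
    )
  })
}

#' Score pre-aligned peptide pairs
#'
#' Peptide-only mode: treats each (source, target) peptide pair as already
#' aligned, gap-free and equal-length -- e.g. the +/-7 flanking windows of
#' validated cross-reactive epitopes -- and computes the same per-site
#' statistics as the full pipeline without needing any proteome. Whitespace
#' inside peptides (a typesetting artifact in printed tables) is stripped.
#'
#' @param pairs Tibble with columns `source_peptide`, `target_peptide`
#'   (other columns are carried through).
#' @param site_pos 1-based phosphosite position within the peptides
#'   (default 8, the centre of a 15-mer).
#' @inheritParams evaluate_site
#' @return `pairs` plus `identity_run`, `best_strict`, `best_relaxed` and
#'   `qualifies_at_<L>` columns.
#' @examples
#' evaluate_peptide_pairs(validated_epitope_pairs())
#' @export
evaluate_peptide_pairs <- function(pairs, site_pos = 8L, cutoffs = 6:11,
                                   groups = similarity_groups(),
                                   allow_conservative = TRUE) {
  cutoffs <- sort(unique(as.integer(cutoffs)))
  src <- gsub("\\s", "", pairs$source_peptide)
  tgt <- gsub("\\s", "", pairs$target_peptide)
  stats <- purrr::map2_dfr(src, tgt, function(a, b) {
    bw <- best_window_lengths(a, b, site_pos, cutoffs, groups,
                              allow_conservative)
    tibble::tibble(
      identity_run = identity_run(a, b, site_pos),
      best_strict = bw$best_strict,
      best_relaxed = bw$best_relaxed,
      !!!qualifies_cols(bw$best_relaxed, cutoffs)
    )
  })
  dplyr::bind_cols(pairs, stats)
}
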