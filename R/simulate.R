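#' Plant specifications for a synthetic bundle
#'
#' Convenience constructor for the plant table consumed by
#' [generate_bundle()]. Each row plants one phosphosite with a designed
#' conservation outcome in the target species:
#'
#' * `level` (0-11): the intended maximum qualifying window length.
#'   Levels 1-5 plant an identical run shorter than the smallest cutoff
#'   (expected best 0); level 0 mutates the site residue itself.
#' * `conservative_sub`: the planted window reaches `level` only through a
#'   single in-group substitution placed at distance >= 2 from the site
#'   (so the strict statistic falls below `level`). Requires `level >= 6`.
#' * `break_adjacency`: a conservative substitution is placed at distance 1
#'   from the site, immediately outside an identical run of length `level`;
#'   the adjacency rule must refuse it, capping qualification at `level`
#'   (an implementation ignoring adjacency would report `level + 1`).
#'   Requires `6 <= level <= 10`: at level 11 the violating window would
#'   exceed the largest cutoff and the plant could not demonstrate anything.
#' * `stale_accession`: the catalog row carries an outdated protein
#'   accession absent from the proteome, forcing the gene-symbol rescue
#'   path.
#'
#' @param level Integer vector of planted levels (recycled against the
#'   flags).
#' @param conservative_sub,break_adjacency,stale_accession Logical vectors.
#' @return Tibble of plants.
#' @export
plant_spec <- function(level, conservative_sub = FALSE,
                       break_adjacency = FALSE, stale_accession = FALSE) {
  out <- tibble::tibble(
    level = as.integer(level),
    conservative_sub = conservative_sub,
    break_adjacency = break_adjacency,
    stale_accession = stale_accession
  )
  validate_plants(out)
  out
}

validate_plants <- function(plants) {
  if (any(plants$level < 0L | plants$level > 11L)) {
    abort("planted levels must lie in 0..11")
  }
  if (any(plants$conservative_sub & plants$break_adjacency)) {
    abort("a plant cannot be both `conservative_sub` and `break_adjacency`")
  }
  if (any((plants$conservative_sub | plants$break_adjacency) &
          plants$level < 6L)) {
    abort("substitution plants need level >= 6 (infeasible plant)")
  }
  if (any(plants$break_adjacency & plants$level > 10L)) {
    abort("`break_adjacency` plants need level <= 10 (infeasible plant)")
  }
  invisible(plants)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# In-group partner used when a plant needs a conservative substitution.
CONS_PARTNER <- c(
  I = "L", L = "I", V = "M", M = "V", F = "W", W = "F", Y = "F",
  K = "R", R = "K", H = "K", D = "E", E = "D", S = "T", T = "S",
  N = "Q", Q = "N", A = "G", G = "A"
)

# A residue that is neither identical nor conservative relative to `res`.
hard_mismatch <- function(res, groups) {
  for (cand in c("P", "C", "D", "K", "F", "G", "W")) {
    if (cand != res && !is_conservative(groups, res, cand)) return(cand)
  }
  stop("unreachable")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Construction-side expectation: best strict/relaxed window lengths and the
# +/-7 identity run, by direct enumeration over the planted protein pair
# (no alignment involved -- the sequences are built position-matched).
expected_outcome <- function(src, tgt, site, cutoffs, groups) {
  n <- nchar(src)
  sc <- strsplit(src, "", fixed = TRUE)[[1]]
  tc <- strsplit(tgt, "", fixed = TRUE)[[1]]
  eq <- sc == tc
  best_s <- 0L
  best_r <- 0L
  for (L in cutoffs) {
    for (s in max(1L, site - L + 1L):min(site, n - L + 1L)) {
      idx <- s:(s + L - 1L)
      mis <- idx[!eq[idx]]
      if (length(mis) == 0L) {
        best_s <- max(best_s, L)
        best_r <- max(best_r, L)
      } else if (length(mis) == 1L && abs(mis - site) >= 2L &&
                 is_conservative(groups, sc[mis], tc[mis])) {
        best_r <- max(best_r, L)
      }
    }
  }
  lo <- site
  while (lo > max(1L, site - 7L) && eq[lo - 1L]) lo <- lo - 1L
  hi <- site
  while (hi < min(n, site + 7L) && eq[hi + 1L]) hi <- hi + 1L
  run <- if (!eq[site]) 0L else hi - lo + 1L
  list(best_strict = best_s, best_relaxed = best_r, identity_run = run)
}

#' Generate a synthetic end-to-end input bundle
#'
#' Builds a self-contained toy data set -- phosphosite catalog, source and
#' target proteomes, identifier maps and a ranked ortholog table -- in which
#' every site has a designed conservation outcome, so the full pipeline can
#' be validated by parameter recovery with no external downloads. Each
#' planted site embeds a designed neighbourhood (an identity span bounded
#' by non-conservative mismatches, optionally carrying one in-group
#' substitution) into random flanking context; the construction-side
#' expectations are recorded alongside. Random context is re-drawn if it
#' ever creates a second occurrence of a site's core peptide, protecting
#' the unambiguous-anchoring contract. Output is deterministic under
#' `seed`. The ortholog table also carries one low-rank decoy pair, which
#' the default rank filter must drop.
#'
#' @param plants Plant table from [plant_spec()].
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param sites_per_gene Planted sites hosted on each source gene.
#' @param flank_context_length Random context residues around each designed
#'   neighbourhood (default 30).
#' @param target_isoforms_per_gene Isoforms per target gene (extra isoforms
#'   are N-terminally extended copies; every isoform carries the same
#'   planted outcome).
#' @param source_organism Organism label written into the catalog.
#' @param groups [similarity_groups()] used both to place conservative
#'   substitutions and to compute expectations.
#' @return A list of class `synthetic_bundle`: `catalog`,
#'   `source_proteins`, `target_proteins`, `source_aliases`,
#'   `target_aliases`, `ortholog_pairs`, `expected` (one row per planted
#'   site with `expected_best_strict`, `expected_best_relaxed`,
#'   `expected_identity_run`), `plants`, `seed`.
#' @examples
#' b <- generate_bundle(plant_spec(c(0, 6, 9, 11)), seed = 42)
#' b$expected
#' @export
generate_bundle <- function(plants, seed = 1L, sites_per_gene = 1L,
                            flank_context_length = 30L,
                            target_isoforms_per_gene = 1L,
                            source_organism = "human",
                            groups = similarity_groups()) {
  validate_plants(plants)
  n_sites <- nrow(plants)
  n_genes <- ceiling(n_sites / sites_per_gene)
  margin <- max(15L, as.integer(flank_context_length) %/% 2L)
  spacing <- 2L * margin + 5L
  cutoffs <- 6:11

  with_seed(seed, {
    catalog <- list()
    src_prot <- list()
    tgt_prot <- list()
    expected <- list()
    pairs <- list()
    plant_i <- 0L

    for (g in seq_len(n_genes)) {
      gene_plants <- plants[(plant_i + 1L):min(plant_i + sites_per_gene, n_sites), ,
                            drop = FALSE]
      plant_i <- plant_i + nrow(gene_plants)
      k <- nrow(gene_plants)
      sites <- margin + 1L + (seq_len(k) - 1L) * spacing
      len <- sites[k] + margin
      sym <- sprintf("sgene%d", g)
      gid <- sprintf("SG%03d", g)
      acc <- sprintf("SP%03d.1", g)
      tgid <- sprintf("TG%03d", g)
      tacc <- sprintf("TP%03d.1", g)

      for (attempt in 1:50) {
        sc <- sample(AA20, len, replace = TRUE)
        tc_extra <- list()
        for (j in seq_len(k)) {
          s <- sites[j]
          sc[s] <- sample(c("S", "T", "Y"), 1L)
          lev <- gene_plants$level[j]
          if (gene_plants$conservative_sub[j]) {
            # substitution position must carry a grouped residue
            sc[s + 2L] <- sample(names(CONS_PARTNER), 1L)
          }
          if (gene_plants$break_adjacency[j]) {
            sc[s + 1L] <- sample(names(CONS_PARTNER), 1L)
          }
        }
        tc <- sc
        for (j in seq_len(k)) {
          s <- sites[j]
          lev <- gene_plants$level[j]
          if (lev == 0L) {
            tc[s] <- hard_mismatch(sc[s], groups)
            next
          }
          if (gene_plants$break_adjacency[j]) {
            # identical run of `lev` ending at the site, conservative
            # substitution immediately right of the site, hard bounds
            span <- c(s - lev + 1L, s)
            tc[s + 1L] <- CONS_PARTNER[[sc[s + 1L]]]
            tc[span[1] - 1L] <- hard_mismatch(sc[span[1] - 1L], groups)
            tc[s + 2L] <- hard_mismatch(sc[s + 2L], groups)
          } else {
            half <- (lev - 1L) %/% 2L
            span <- c(s - half, s - half + lev - 1L)
            if (gene_plants$conservative_sub[j]) {
              tc[s + 2L] <- CONS_PARTNER[[sc[s + 2L]]]
            }
            tc[span[1] - 1L] <- hard_mismatch(sc[span[1] - 1L], groups)
            tc[span[2] + 1L] <- hard_mismatch(sc[span[2] + 1L], groups)
          }
        }
        src_seq <- paste(sc, collapse = "")
        tgt_seq <- paste(tc, collapse = "")
        cores <- vapply(sites, function(s)
          gsub("_", "", flank_at(src_seq, s), fixed = TRUE), "")
        n_occ <- vapply(cores, function(p)
          length(peptide_occurrences(src_seq, p)), 1L)
        if (all(n_occ == 1L)) break
      }

      src_prot[[g]] <- tibble::tibble(
        accession = acc, sequence = src_seq, gene_id = gid
      )
      tgt_rows <- tibble::tibble(
        accession = tacc, sequence = tgt_seq, gene_id = tgid
      )
      if (target_isoforms_per_gene > 1L) {
        for (iso in 2:target_isoforms_per_gene) {
          ext <- paste(sample(AA20, 5L * (iso - 1L), replace = TRUE),
                       collapse = "")
          tgt_rows <- dplyr::bind_rows(tgt_rows, tibble::tibble(
            accession = sprintf("TP%03d.%d", g, iso),
            sequence = paste0(ext, tgt_seq),
            gene_id = tgid
          ))
        }
      }
      tgt_prot[[g]] <- tgt_rows
      pairs[[g]] <- tibble::tibble(
        source_gene_id = gid, target_gene_id = tgid,
        rank = if (g %% 2L == 1L) "high" else "moderate"
      )

      for (j in seq_len(k)) {
        s <- sites[j]
        lab <- paste0(sc[s], s, "-p")
        stale <- gene_plants$stale_accession[j]
        catalog[[length(catalog) + 1L]] <- tibble::tibble(
          gene_symbol = sym,
          protein_accession = if (stale) sprintf("XX%03d.9", g) else acc,
          organism = source_organism,
          residue = sc[s],
          position = s,
          flank_peptide = flank_at(src_seq, s),
          antibody_ids = list(sprintf("#%d", 1000L + length(catalog))),
          site_label = lab,
          center_matches = TRUE
        )
        exp <- expected_outcome(src_seq, tgt_seq, s, cutoffs, groups)
        lev <- gene_plants$level[j]
        want <- if (lev >= 6L) lev else 0L
        if (gene_plants$conservative_sub[j]) {
          stopifnot(exp$best_relaxed == want)
        } else if (gene_plants$break_adjacency[j]) {
          stopifnot(exp$best_relaxed == want, exp$best_strict == want)
        } else {
          stopifnot(exp$best_strict == want, exp$best_relaxed == want)
        }
        expected[[length(expected) + 1L]] <- tibble::tibble(
          gene_symbol = sym, source_gene_id = gid, site_label = lab,
          source_accession = acc, target_gene_id = tgid,
          level = lev,
          conservative_sub = gene_plants$conservative_sub[j],
          break_adjacency = gene_plants$break_adjacency[j],
          stale_accession = stale,
          expected_best_strict = exp$best_strict,
          expected_best_relaxed = exp$best_relaxed,
          expected_identity_run = exp$identity_run
        )
      }
    }

    catalog <- dplyr::bind_rows(catalog)
    src_prot <- dplyr::bind_rows(src_prot)
    tgt_prot <- dplyr::bind_rows(tgt_prot)
    pairs <- dplyr::bind_rows(pairs)
    # low-rank decoy: must be dropped by the default rank filter
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      source_gene_id = "SG001", target_gene_id = "TGDECOY", rank = "low"
    ))
    pairs$rank <- factor(pairs$rank, levels = c("low", "moderate", "high"),
                         ordered = TRUE)

    structure(
      list(
        catalog = catalog,
        source_proteins = src_prot,
        target_proteins = tgt_prot,
        source_aliases = tibble::tibble(
          alias = unique(catalog$gene_symbol),
          gene_id = sprintf("SG%03d", match(unique(catalog$gene_symbol),
                                            unique(catalog$gene_symbol)))
        ),
        target_aliases = tibble::tibble(
          alias = sprintf("tgene%d", seq_len(n_genes)),
          gene_id = sprintf("TG%03d", seq_len(n_genes))
        ),
        ortholog_pairs = pairs,
        expected = dplyr::bind_rows(expected),
        plants = plants,
        seed = seed
      ),
      class = "synthetic_bundle"
    )
  })
}

#' Write a synthetic bundle to disk
#'
#' Serialises every bundle component through the package's own writers
#' (catalog in the phosphosite-catalog dialect with a 3-line preamble
#' banner, proteomes as FASTA, maps and ortholog table as TSV) plus a flat
#' key-value pipeline config pointing at the written files, so
#' `run_pipeline(file.path(dir, "config.txt"))` runs end-to-end.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  write_phosphosite_catalog(
    bundle$catalog, p("catalog.tsv"),
    preamble = c("Synthetic phosphosite catalog", "for pipeline validation", "")
  )
  write_protein_fasta(bundle$source_proteins, p("source_proteome.fasta"))
  write_protein_fasta(bundle$target_proteins, p("target_proteome.fasta"))

  src_map <- dplyr::bind_rows(
    bundle$source_aliases,
    tibble::tibble(alias = bundle$source_proteins$accession,
                   gene_id = bundle$source_proteins$gene_id)
  )
  tgt_map <- dplyr::bind_rows(
    bundle$target_aliases,
    tibble::tibble(alias = bundle$target_proteins$accession,
                   gene_id = bundle$target_proteins$gene_id)
  )
  readr::write_tsv(src_map, p("source_gene_map.tsv"), progress = FALSE)
  readr::write_tsv(tgt_map, p("target_gene_map.tsv"), progress = FALSE)
  readr::write_tsv(
    dplyr::mutate(bundle$ortholog_pairs, rank = as.character(.data$rank)),
    p("orthologs.tsv"), progress = FALSE
  )
  readr::write_tsv(bundle$expected, p("expected.tsv"), progress = FALSE)

  cfg <- c(
    paste("catalog =", p("catalog.tsv")),
    paste("source_fasta =", p("source_proteome.fasta")),
    paste("target_fasta =", p("target_proteome.fasta")),
    paste("source_gene_map =", p("source_gene_map.tsv")),
    paste("target_gene_map =", p("target_gene_map.tsv")),
    paste("ortholog_table =", p("orthologs.tsv")),
    paste("source_organisms =", unique(bundle$catalog$organism)[1]),
    "min_rank = moderate",
    "require_antibody = true",
    paste("report =", p("report.tsv")),
    paste("summary =", p("summary.tsv"))
  )
  readr::write_lines(cfg, p("config.txt"))

  invisible(list(
    catalog = p("catalog.tsv"),
    source_fasta = p("source_proteome.fasta"),
    target_fasta = p("target_proteome.fasta"),
    source_gene_map = p("source_gene_map.tsv"),
    target_gene_map = p("target_gene_map.tsv"),
    ortholog_table = p("orthologs.tsv"),
    expected = p("expected.tsv"),
    config = p("config.txt")
  ))
}
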