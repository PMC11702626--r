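#' Read a flat key-value pipeline config
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Relative paths are resolved against the config file's directory.
#' Unset keys take the [pipeline_config()] defaults.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) {
    abort(paste0("cannot parse config line: ", lines[bad][1]))
  }
  vals <- setNames(
    trimws(vapply(kv, `[`, "", 3)),
    vapply(kv, `[`, "", 2)
  )
  base <- dirname(path)
  as_path <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (!nzchar(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  as_flag <- function(x, default) {
    if (is.null(x)) return(default)
    tolower(x) %in% c("true", "yes", "1")
  }
  g <- function(k) if (k %in% names(vals)) vals[[k]] else NULL
  pipeline_config(
    catalog = as_path(g("catalog")),
    source_fasta = as_path(g("source_fasta")),
    target_fasta = as_path(g("target_fasta")),
    source_gene_map = as_path(g("source_gene_map")),
    target_gene_map = as_path(g("target_gene_map")),
    ortholog_table = as_path(g("ortholog_table")),
    paralog_table = as_path(g("paralog_table")),
    source_organisms = if (is.null(g("source_organisms"))) c("human", "mouse", "rat")
      else trimws(strsplit(g("source_organisms"), ",")[[1]]),
    min_rank = g("min_rank") %||% "moderate",
    cutoffs = if (is.null(g("cutoffs"))) 6:11
      else as.integer(trimws(strsplit(g("cutoffs"), ",")[[1]])),
    allow_conservative = as_flag(g("allow_conservative"), TRUE),
    similarity = g("similarity") %||% "classic",
    isoforms = g("isoforms") %||% "all",
    require_antibody = as_flag(g("require_antibody"), TRUE),
    matrix = g("matrix") %||% "BLOSUM62",
    gap_open = as.numeric(g("gap_open") %||% -10),
    gap_extend = as.numeric(g("gap_extend") %||% -0.5),
    report = as_path(g("report")),
    summary = as_path(g("summary"))
  )
}

#' Pipeline configuration
#'
#' Collects every input path and tunable of the end-to-end screen. The
#' pipeline is deterministic: no key introduces randomness, and re-running
#' the same config byte-reproduces all outputs.
#'
#' @param catalog Phosphosite catalog path.
#' @param source_fasta,target_fasta Proteome FASTA paths.
#' @param source_gene_map,target_gene_map Alias-to-gene tables (symbols and
#'   accessions).
#' @param ortholog_table Ranked ortholog-pair table.
#' @param paralog_table Optional second pair table with identical semantics
#'   (paralog expansion), off by default.
#' @param source_organisms Organisms admitted from the catalog.
#' @param min_rank Ortholog confidence filter (`"high"`/`"moderate"`/`"low"`).
#' @param cutoffs Window cutoffs, within 6..11.
#' @param allow_conservative Permit the one-conservative-substitution
#'   relaxation.
#' @param similarity `"classic"` or `"blosum62_positive"`.
#' @param isoforms `"all"` or `"longest"` target isoforms.
#' @param require_antibody Keep only catalog rows with an antibody.
#' @param matrix,gap_open,gap_extend Alignment scoring parameters.
#' @param report,summary Optional output paths (TSV).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(catalog = NULL, source_fasta = NULL,
                            target_fasta = NULL, source_gene_map = NULL,
                            target_gene_map = NULL, ortholog_table = NULL,
                            paralog_table = NULL,
                            source_organisms = c("human", "mouse", "rat"),
                            min_rank = "moderate", cutoffs = 6:11,
                            allow_conservative = TRUE,
                            similarity = "classic",
                            isoforms = "all", require_antibody = TRUE,
                            matrix = "BLOSUM62", gap_open = -10,
                            gap_extend = -0.5,
                            report = NULL, summary = NULL) {
  cutoffs <- sort(unique(as.integer(cutoffs)))
  if (any(cutoffs < 6L | cutoffs > 11L)) {
    abort("cutoffs must lie within 6..11")
  }
  structure(
    list(
      catalog = catalog, source_fasta = source_fasta,
      target_fasta = target_fasta, source_gene_map = source_gene_map,
      target_gene_map = target_gene_map, ortholog_table = ortholog_table,
      paralog_table = paralog_table,
      source_organisms = source_organisms,
      min_rank = match.arg(min_rank, c("high", "moderate", "low")),
      cutoffs = cutoffs,
      allow_conservative = isTRUE(allow_conservative),
      similarity = match.arg(similarity, c("classic", "blosum62_positive")),
      isoforms = match.arg(isoforms, c("all", "longest")),
      require_antibody = isTRUE(require_antibody),
      matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
      report = report, summary = summary
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(format_pipeline_config(x), sep = "\n")
  invisible(x)
}

#' Render a config as flat key-value lines
#'
#' @param config A `pipeline_config`.
#' @return Character vector of `key = value` lines (paths included when
#'   set), suitable for writing back to a config file.
#' @export
format_pipeline_config <- function(config) {
  fmt <- function(k) {
    v <- config[[k]]
    if (is.null(v)) return(NULL)
    if (is.logical(v)) v <- tolower(as.character(v))
    paste0(k, " = ", paste(v, collapse = ","))
  }
  unlist(lapply(names(config), fmt))
}

read_proteome <- function(fasta_path, map_path) {
  prots <- read_protein_fasta(fasta_path)
  map <- read_gene_map(map_path)
  map <- map[!duplicated(tolower(map$alias)), ]
  prots$gene_id <- map$gene_id[match(tolower(prots$accession),
                                     tolower(map$alias))]
  prots$gene_id[is.na(prots$gene_id)] <- paste0(
    "unmapped:", prots$accession[is.na(prots$gene_id)]
  )
  prots
}

#' Run the full cross-reactivity screen
#'
#' Executes the five pipeline stages end-to-end: (1) catalog parsing and
#' site anchoring on the source proteome (with gene-symbol rescue of
#' outdated accessions), (2) gene-identifier resolution, (3) ortholog
#' expansion under the confidence-rank filter, (4) global alignment of
#' each anchored source protein against every selected target isoform, and
#' (5) window-conservation scoring at each cutoff. Emits a per-site report
#' and a per-cutoff summary, and logs a machine-parseable stage funnel
#' (`key=value` lines).
#'
#' @param config A `pipeline_config`, or the path of a flat key-value
#'   config file.
#' @param quiet Suppress the funnel log.
#' @return An object of class `crossphos_run`: list with `report` (per
#'   site x isoform tibble), `summary` (per-cutoff counts), `funnel`
#'   (named integer of stage counts), `anchor_tally`, and `config`.
#'   [glance()] returns the funnel as a one-row tibble; [autoplot()] draws
#'   the summary.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  }
  stopifnot(inherits(config, "pipeline_config"))
  for (k in c("catalog", "source_fasta", "target_fasta", "source_gene_map",
              "target_gene_map", "ortholog_table")) {
    if (is.null(config[[k]])) abort(paste0("config key `", k, "` is required"))
    if (!file.exists(config[[k]])) {
      abort(paste0("input not readable: ", config[[k]], " (", k, ")"))
    }
  }
  scheme <- scoring_scheme(config$matrix, config$gap_open, config$gap_extend)
  groups <- similarity_groups(config$similarity)

  catalog <- read_phosphosite_catalog(
    config$catalog, organisms = config$source_organisms,
    require_antibody = config$require_antibody
  )
  source_index <- build_gene_index(
    read_proteome(config$source_fasta, config$source_gene_map),
    read_gene_map(config$source_gene_map)
  )
  target_index <- build_gene_index(
    read_proteome(config$target_fasta, config$target_gene_map),
    read_gene_map(config$target_gene_map)
  )
  pairs <- read_ortholog_pairs(config$ortholog_table, min_rank = "low")
  paralogs <- if (!is.null(config$paralog_table)) {
    read_ortholog_pairs(config$paralog_table, min_rank = "low")
  }

  anchored <- anchor_sites(catalog, source_index)
  if (nrow(anchored) == 0L) {
    warn("no catalog site could be anchored; writing an empty report")
  }
  resolved <- resolve_genes(anchored, source_index)
  resolved_ok <- resolved[resolved$resolve_status == "ok", , drop = FALSE]
  mapped <- expand_orthologs(resolved_ok, pairs, config$min_rank, paralogs)
  results <- evaluate_conservation(
    mapped, source_index, target_index, scheme = scheme,
    cutoffs = config$cutoffs, groups = groups,
    allow_conservative = config$allow_conservative,
    isoforms = config$isoforms
  )
  summary <- summarize_conservation(results, config$cutoffs)

  min_cut <- min(config$cutoffs)
  qcol <- paste0("qualifies_at_", min_cut)
  site_key <- paste(results$source_organism, results$source_gene,
                    results$site_label)
  funnel <- c(
    records_read = nrow(catalog),
    anchored = nrow(anchored),
    gene_resolved = nrow(resolved_ok),
    ortholog_mapped = nrow(mapped),
    aligned = nrow(results),
    qualifying_sites = dplyr::n_distinct(site_key[results[[qcol]]])
  )
  if (!quiet) {
    inform(paste0(names(funnel), "=", funnel, collapse = "\n"))
  }
  if (!is.null(config$report)) write_report(results, config$report)
  if (!is.null(config$summary)) {
    readr::write_tsv(summary, config$summary, progress = FALSE)
  }
  structure(
    list(report = results, summary = summary, funnel = funnel,
         anchor_tally = attr(anchored, "skip_tally"),
         catalog_tally = attr(catalog, "skip_tally"),
         config = config),
    class = "crossphos_run"
  )
}

#' @export
print.crossphos_run <- function(x, ...) {
  cat("<crossphos_run>\n")
  cat(paste0("  ", names(x$funnel), " = ", x$funnel), sep = "\n")
  print(x$summary)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `crossphos_run`.
#' @param ... Unused.
#' @export
glance.crossphos_run <- function(x, ...) {
  tibble::as_tibble(as.list(x$funnel))
}

#' @rdname run_pipeline
#' @export
tidy.crossphos_run <- function(x, ...) {
  x$report
}
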