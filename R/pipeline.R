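# End-to-end orchestration: simulate a fixture directory, or run
# curation + enrichment over files on disk and emit a machine-readable
# run report.

#' Write a simulated experiment as a fixture directory
#'
#' Generates an experiment with [generate_experiment()] and writes the
#' five pipeline input files: `psm.tsv`, `design.yaml`,
#' `contaminants.txt`, `truth.tsv`, and the resolved configuration
#' (including the seed) as `config.yaml`. Rerunning with the same
#' configuration reproduces the files byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, as.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- generate_experiment(config)
  paths <- c(
    psm = file.path(out_dir, "psm.tsv"),
    design = file.path(out_dir, "design.yaml"),
    contaminants = file.path(out_dir, "contaminants.txt"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_psm_table(exp$psm, paths[["psm"]])
  write_design(exp$design, paths[["design"]])
  write_contaminant_list(exp$truth, paths[["contaminants"]])
  write_truth_table(exp$truth, paths[["truth"]])
  yaml::write_yaml(unclass(config), paths[["config"]])
  invisible(paths)
}

#' Run curation and enrichment end to end
#'
#' Reads the PSM table, design, contaminant list and (optionally) GMT
#' collections, curates the interactome, scores each collection by
#' over-representation of the curated hit list, writes all stage outputs
#' to `out_dir`, and returns the run report. Outputs are
#' `interactome.tsv`, `enrichment_<collection>.tsv`, `network.sif`,
#' `network.graphml`, and `report.json`. The report contains only
#' quantities re-derivable from those files (set sizes, parameters,
#' input checksums, package version) — no timestamps — so a rerun on the
#' same inputs is byte-identical.
#'
#' @param psm_path Path to the PSM TSV.
#' @param design_path Path to the design YAML.
#' @param contaminants_path Path to the contaminant list, or `NULL`.
#' @param gmt_paths Named character vector of GMT paths (names label the
#'   collections in the output files); may be empty.
#' @param out_dir Output directory (created if needed).
#' @param bait_id Bait protein identifier, or `NULL`.
#' @param universe Optional character vector of background symbols for
#'   enrichment; the default is the detected proteome within each
#'   collection ([detected_universe()]).
#' @inheritParams curate_interactome
#' @inheritParams enrich
#' @return The run report (a list of class `apms_report`), invisibly.
#' @export
run_all <- function(psm_path, design_path, contaminants_path = NULL,
                    gmt_paths = character(), out_dir,
                    bait_id = NULL, threshold = 2, pseudocount = 0.5,
                    min_count = 2, null_min_count = 2, ge = FALSE,
                    drop_contaminants = FALSE, allow_missing_null = FALSE,
                    universe = NULL, min_set = 3, max_set = 2000) {
  inputs <- c(psm = psm_path, design = design_path,
              contaminants = contaminants_path, gmt_paths)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    abort_config(sprintf("input file(s) not found: %s",
                         paste(missing, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  psm <- read_psm_table(psm_path)
  design <- read_design(design_path)
  contaminants <- if (is.null(contaminants_path)) character()
    else read_contaminant_list(contaminants_path)

  curated <- curate_interactome(
    psm, design, contaminants, bait_id = bait_id,
    threshold = threshold, pseudocount = pseudocount, min_count = min_count,
    null_min_count = null_min_count, ge = ge,
    drop_contaminants = drop_contaminants,
    allow_missing_null = allow_missing_null
  )

  tab <- interactome_table(curated)
  readr::write_tsv(tab, file.path(out_dir, "interactome.tsv"), quote = "none",
                   eol = "\n", progress = FALSE)
  if (length(curated$interactome) > 0 && !is.null(bait_id)) {
    write_network_sif(curated, bait_id, file.path(out_dir, "network.sif"))
    write_network_graphml(curated, bait_id, file.path(out_dir, "network.graphml"))
  }

  hit_symbols <- unique(tab$gene_symbol[nzchar(tab$gene_symbol)])
  if (length(gmt_paths) > 0 && is.null(names(gmt_paths))) {
    names(gmt_paths) <- sprintf("collection%d", seq_along(gmt_paths))
  }
  enrichment_sizes <- list()
  for (nm in names(gmt_paths) %||% character()) {
    collection <- read_gmt(gmt_paths[[nm]])
    uni <- universe %||% detected_universe(psm, collection)
    res <- enrich(hit_symbols, uni, collection,
                  min_set = min_set, max_set = max_set)
    readr::write_tsv(res, file.path(out_dir, sprintf("enrichment_%s.tsv", nm)),
                     quote = "none", eol = "\n", progress = FALSE)
    enrichment_sizes[[nm]] <- list(
      sets_tested = nrow(res),
      significant_q_05 = sum(res$q < 0.05)
    )
  }

  report <- list(
    tool = "apmscurate",
    version = as.character(utils::packageVersion("apmscurate")),
    parameters = curated$params,
    inputs = as.list(tools::md5sum(inputs)),
    sizes = list(
      hits_bcs = length(curated$hits_bcs),
      hits_cu = length(curated$hits_cu),
      interactome = length(curated$interactome),
      core = length(curated$core),
      bcs_only = length(curated$bcs_only),
      cu_only = length(curated$cu_only),
      null_removed = length(curated$null_removed),
      contaminant_overlap = length(curated$contaminant_overlap)
    ),
    overlap_percent = curated$overlap_percent,
    bait = if (!is.null(curated$bait)) list(
      protein_id = curated$bait$protein_id,
      passed = any(curated$bait$records$pass %||% FALSE),
      null_removed = curated$bait$null_removed
    ),
    enrichment = enrichment_sizes
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(report) <- "apms_report"
  attr(report, "curated") <- curated
  invisible(report)
}

#' @export
print.apms_report <- function(x, ...) {
  cat(sprintf("apmscurate run report (v%s)\n", x$version))
  s <- x$sizes
  cat(sprintf("  interactome %d (core %d; BCS-only %d, CU-only %d)\n",
              s$interactome, s$core, s$bcs_only, s$cu_only))
  cat(sprintf("  null-removed %d; contaminant overlap %d (%.1f%%)\n",
              s$null_removed, s$contaminant_overlap, x$overlap_percent))
  invisible(x)
}
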