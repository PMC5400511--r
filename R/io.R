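# Readers and writers for every external format the pipeline touches.
# All tabular formats are strict TSV: tab-separated, no quoting, LF line
# endings, UTF-8 — matching the GMT convention and avoiding dialect
# sniffing. Protein identifiers are treated as opaque (never case-folded);
# gene symbols are case-folded only where gene-set matching requires it.

psm_columns <- c("protein_id", "gene_symbol", "psm", "sample_id")

#' Read a long-form PSM count table
#'
#' Reads a TSV with header `protein_id  gene_symbol  psm  sample_id`.
#' Duplicate (`protein_id`, `sample_id`) rows are summed at read time, so
#' the result has one row per protein per sample. A missing gene symbol is
#' stored as the empty string.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id`, `gene_symbol`, `psm`
#'   (integer), `sample_id`.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) abort_value(sprintf("PSM table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(psm_columns, names(raw))
  if (length(missing) > 0) {
    abort_value(sprintf("PSM table %s is missing column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warning(sprintf("PSM table %s contains a header but no data rows", path))
    return(tibble::tibble(protein_id = character(), gene_symbol = character(),
                          psm = integer(), sample_id = character()))
  }
  psm_num <- suppressWarnings(as.numeric(raw$psm))
  bad <- which(is.na(psm_num) | psm_num < 0 | psm_num != trunc(psm_num))
  if (length(bad) > 0) {
    abort_value(sprintf(
      "PSM table %s: psm must be a nonnegative integer (first offending value '%s' on line %d)",
      path, raw$psm[bad[1]], bad[1] + 1L  # +1 for the header line
    ))
  }
  out <- tibble::tibble(
    protein_id = raw$protein_id,
    gene_symbol = ifelse(is.na(raw$gene_symbol), "", raw$gene_symbol),
    psm = as.integer(psm_num),
    sample_id = raw$sample_id
  )
  out |>
    dplyr::group_by(.data$protein_id, .data$sample_id) |>
    dplyr::summarise(
      gene_symbol = .data$gene_symbol[1],
      psm = as.integer(sum(.data$psm)),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(psm_columns))
}

#' Write a PSM count table
#'
#' @param psm Tibble with columns `protein_id`, `gene_symbol`, `psm`,
#'   `sample_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psm, path) {
  stopifnot(all(psm_columns %in% names(psm)))
  readr::write_tsv(psm[, psm_columns], path, quote = "none", eol = "\n",
                   progress = FALSE)
  invisible(path)
}

#' Read an experiment-design YAML file
#'
#' The file is a mapping from sample identifier to arm assignment, e.g.
#' ```yaml
#' WT_BCS_minus_1: {genotype: WT, condition: BCS, peptide: minus}
#' NULL_minus_1:   {genotype: "NULL", condition: "NA", peptide: minus}
#' ```
#' `genotype` must be `WT` or `NULL`, `condition` one of `BCS`, `CU`, `NA`
#' (the latter for bait-null samples), and `peptide` `plus` or `minus`.
#'
#' @param path Path to the YAML file.
#' @return A tibble with columns `sample_id`, `genotype`, `condition`,
#'   `peptide`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) abort_value(sprintf("design file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) abort_config(sprintf("design file %s defines no samples", path))
  norm <- function(x) {
    # unquoted NULL/NA parse as R NULL/NA; map them back to their strings
    if (is.null(x)) return("NULL")
    x <- as.character(x)
    ifelse(is.na(x), "NA", x)
  }
  design <- tibble::tibble(
    sample_id = names(raw),
    genotype = unname(vapply(raw, function(s) norm(s$genotype), character(1))),
    condition = unname(vapply(raw, function(s) norm(s$condition), character(1))),
    peptide = unname(vapply(raw, function(s) norm(s$peptide), character(1)))
  )
  validate_design(design, path)
  design
}

validate_design <- function(design, label = "design") {
  bad_geno <- setdiff(unique(design$genotype), c("WT", "NULL"))
  bad_cond <- setdiff(unique(design$condition), c("BCS", "CU", "NA"))
  bad_pep <- setdiff(unique(design$peptide), c("plus", "minus"))
  if (length(c(bad_geno, bad_cond, bad_pep)) > 0) {
    abort_config(sprintf(
      "%s contains invalid arm values: %s",
      label, paste(c(bad_geno, bad_cond, bad_pep), collapse = ", ")
    ))
  }
  if (anyDuplicated(design$sample_id)) {
    abort_config(sprintf("%s contains duplicated sample identifiers", label))
  }
  invisible(design)
}

#' Write an experiment-design YAML file
#'
#' @param design Design tibble (see [read_design()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  entries <- lapply(seq_len(nrow(design)), function(i) {
    list(genotype = design$genotype[i], condition = design$condition[i],
         peptide = design$peptide[i])
  })
  names(entries) <- design$sample_id
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' Read a simulation truth table
#'
#' @param path Path to a TSV with header
#'   `protein_id  label  condition_membership  contaminant`.
#' @return A tibble in the layout written by [write_truth_table()].
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      label = readr::col_character(),
      condition_membership = readr::col_character(),
      contaminant = readr::col_logical()
    ),
    progress = FALSE
  )
}

#' Write a simulation truth table
#'
#' @param truth Truth tibble from [generate_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path, quote = "none", eol = "\n", progress = FALSE)
  invisible(path)
}

#' Read a contaminant list
#'
#' One identifier per nonblank line; if lines are tab-separated, the first
#' column is taken. Duplicates are removed. An empty file yields an empty
#' set with a warning rather than an error.
#'
#' @param path Path to the list.
#' @return Character vector of unique identifiers.
#' @export
read_contaminant_list <- function(path) {
  if (!file.exists(path)) abort_value(sprintf("contaminant list not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning(sprintf("contaminant list %s is empty", path))
    return(character())
  }
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  unique(ids)
}

#' Write a contaminant list
#'
#' Writes the contaminant-flagged proteins of a truth table (or a plain
#' character vector of identifiers), one per line, sorted
#' lexicographically.
#'
#' @param truth Truth tibble from [generate_experiment()], or a character
#'   vector of identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contaminant_list <- function(truth, path) {
  ids <- if (is.character(truth)) truth else truth$protein_id[truth$contaminant]
  con <- file(path, open = "wb")  # binary keeps LF endings everywhere
  on.exit(close(con))
  if (length(ids) > 0) {
    writeLines(sort(unique(ids), method = "radix"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per nonblank line; tab-separated fields are the
#' set name, a free-text description, then the member symbols. Member
#' symbols are case-folded to upper case (gene-set matching downstream is
#' case-insensitive) and deduplicated within a set. A line with fewer than
#' three fields (i.e. a set with no members) is a format error.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   character vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_value(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0) {
    abort_value(sprintf("GMT file %s: line %d has fewer than 3 tab-separated fields",
                        path, line_no[short[1]]))
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  description <- vapply(fields, `[[`, character(1), 2L)
  names(description) <- names(sets)
  gene_set_collection(sets, description)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of member symbols.
#' @param description Optional named character vector of descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(toupper(as.character(s))))
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d sets, median size %s\n",
              length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else "-"))
  invisible(x)
}

#' Write a GMT gene-set collection
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Export a curated interactome as a SIF edge list
#'
#' One `bait  interacts  prey` line per interactor, sorted by prey
#' identifier, suitable for import into Cytoscape.
#'
#' @param interactome A [curate_interactome()] result or a character
#'   vector of prey identifiers.
#' @param bait_id Bait identifier used as the network hub.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_sif <- function(interactome, bait_id, path) {
  preys <- if (inherits(interactome, "curated_interactome")) {
    interactome$interactome
  } else {
    as.character(interactome)
  }
  if (length(preys) == 0) abort_value("cannot export an empty interactome")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(bait_id, "interacts", sort(preys, method = "radix"), sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' Export a curated interactome as GraphML with node annotations
#'
#' Nodes carry `role` (bait/prey), `core` (detected under both copper
#' conditions), `condition` (`core`, `BCS`, or `CU`), and `contaminant`
#' (present on the contaminant list) attributes.
#'
#' @param curated A [curate_interactome()] result.
#' @param bait_id Bait identifier.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(curated, bait_id, path) {
  stopifnot(inherits(curated, "curated_interactome"))
  preys <- curated$interactome
  if (length(preys) == 0) abort_value("cannot export an empty interactome")
  nodes <- data.frame(
    name = c(bait_id, preys),
    role = c("bait", rep("prey", length(preys))),
    core = c(FALSE, preys %in% curated$core),
    condition = c("bait", ifelse(preys %in% curated$core, "core",
                                 ifelse(preys %in% curated$hits_bcs, "BCS", "CU"))),
    contaminant = c(FALSE, preys %in% curated$contaminant_overlap),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = bait_id, to = preys, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
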