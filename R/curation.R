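#' Spectral-count enrichment ratio against the peptide-competition control
#'
#' Computes the ratio of summed PSM counts between the specific IP
#' (no competing peptide, `a`) and the peptide-competition control (`b`)
#' for one protein, and whether it passes the fold-change threshold. The
#' calling rule is:
#' \itemize{
#'   \item `b == 0` and `a >= min_count`: the protein was observed
#'     repeatedly only when the antibody was free — the strongest
#'     qualitative evidence the design offers. Ratio is `Inf` and the
#'     protein passes outright.
#'   \item `b == 0` and `a < min_count`: ratio is computed with the
#'     pseudocount and the threshold applied normally, so single-spectrum
#'     observations do not pass on division noise alone.
#'   \item otherwise: ratio is `(a + pseudocount) / (b + pseudocount)`.
#' }
#' By default passing requires ratio strictly greater than `threshold`
#' (2-fold); set `ge = TRUE` for a greater-or-equal comparison.
#'
#' All arguments are vectorised over `a` and `b`.
#'
#' @param a Summed PSM count in minus-peptide samples (nonnegative integer).
#' @param b Summed PSM count in plus-peptide samples (nonnegative integer).
#' @param pseudocount Nonnegative value added to both counts when forming
#'   the ratio.
#' @param min_count Minimum `a` for the zero-control auto-pass.
#' @param threshold Fold-change threshold.
#' @param ge Use `>=` instead of the default strict `>`.
#' @return A list with numeric `ratio` and logical `pass`.
#' @export
#' @examples
#' enrichment_ratio(10, 4, pseudocount = 0)  # ratio 2.5, pass
#' enrichment_ratio(6, 3, pseudocount = 0)   # ratio 2.0, fails the strict test
enrichment_ratio <- function(a, b, pseudocount = 0.5, min_count = 2,
                             threshold = 2, ge = FALSE) {
  if (any(a < 0) || any(b < 0)) abort_value("PSM counts must be nonnegative")
  check_number(pseudocount, "pseudocount", min = 0)
  check_number(min_count, "min_count", min = 1, integer = TRUE)
  check_number(threshold, "threshold", min = 0, strict_min = TRUE)
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  auto <- b == 0 & a >= min_count
  ratio <- (a + pseudocount) / (b + pseudocount)
  ratio[auto] <- Inf
  cmp <- if (ge) ratio >= threshold else ratio > threshold
  pass <- auto | (!is.na(cmp) & cmp)
  list(ratio = ratio, pass = pass)
}

arm_sums <- function(psm, sample_ids) {
  sub <- psm[psm$sample_id %in% sample_ids, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(protein_id = character(), total = numeric()))
  }
  sub |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(total = sum(.data$psm), .groups = "drop")
}

#' Call specific interactors for one condition by ratio filtering
#'
#' Sums PSM counts within the minus-peptide and plus-peptide wild-type
#' arms of `condition` (across replicate samples), then applies
#' [enrichment_ratio()] to every protein observed (summed PSM >= 1) in the
#' minus-peptide arm. Proteins never seen in the minus-peptide arm get no
#' record and cannot be hits. The bait is evaluated exactly like any prey.
#'
#' @param psm PSM tibble (see [read_psm_table()]).
#' @param design Design tibble (see [read_design()]).
#' @param condition `"BCS"` or `"CU"` (any condition present in the design).
#' @inheritParams enrichment_ratio
#' @return A tibble of ratio records with columns `protein_id`,
#'   `gene_symbol`, `a`, `b`, `ratio`, `pass`, carrying the condition as
#'   attribute `condition`. The hit set is `protein_id[pass]`.
#' @export
call_hits <- function(psm, design, condition, threshold = 2,
                      pseudocount = 0.5, min_count = 2, ge = FALSE) {
  minus_ids <- design$sample_id[design$genotype == "WT" &
                                  design$condition == condition &
                                  design$peptide == "minus"]
  plus_ids <- design$sample_id[design$genotype == "WT" &
                                 design$condition == condition &
                                 design$peptide == "plus"]
  if (length(minus_ids) == 0 || length(plus_ids) == 0) {
    abort_config(sprintf(
      "condition '%s' needs at least one WT minus-peptide and one WT plus-peptide sample",
      condition
    ))
  }
  a_tab <- arm_sums(psm, minus_ids)
  b_tab <- arm_sums(psm, plus_ids)
  a_tab <- a_tab[a_tab$total >= 1, , drop = FALSE]

  b <- b_tab$total[match(a_tab$protein_id, b_tab$protein_id)]
  b[is.na(b)] <- 0
  er <- enrichment_ratio(a_tab$total, b, pseudocount = pseudocount,
                         min_count = min_count, threshold = threshold, ge = ge)

  symbols <- psm$gene_symbol[match(a_tab$protein_id, psm$protein_id)]
  records <- tibble::tibble(
    protein_id = a_tab$protein_id,
    gene_symbol = ifelse(is.na(symbols), "", symbols),
    a = as.numeric(a_tab$total),
    b = as.numeric(b),
    ratio = er$ratio,
    pass = er$pass
  )
  attr(records, "condition") <- condition
  records
}

#' Eliminate proteins recovered from the bait-null control
#'
#' A hit is removed when its summed PSM count across the bait-null
#' (genotype `NULL`) minus-peptide samples reaches `null_min_count`:
#' anything a cell without the bait yields is nonspecific by construction.
#' The default of 2 avoids removals on single stray spectra; set it to 1
#' for removal on any evidence.
#'
#' @param hits Character vector of hit identifiers (e.g.
#'   `records$protein_id[records$pass]` from [call_hits()]).
#' @param psm PSM tibble.
#' @param design Design tibble.
#' @param null_min_count Minimum summed NULL-arm PSM for removal.
#' @param allow_missing_null Permit curation without a bait-null control
#'   (no removal happens); without this flag a design lacking NULL samples
#'   is a configuration error.
#' @return A list with character vectors `curated` and `removed`; the two
#'   are disjoint and their union is `hits`.
#' @export
subtract_null <- function(hits, psm, design, null_min_count = 2,
                          allow_missing_null = FALSE) {
  check_number(null_min_count, "null_min_count", min = 1, integer = TRUE)
  null_ids <- design$sample_id[design$genotype == "NULL" &
                                 design$peptide == "minus"]
  if (length(null_ids) == 0) {
    if (!allow_missing_null) {
      abort_config(paste(
        "design contains no bait-null (genotype NULL) minus-peptide sample;",
        "pass allow_missing_null = TRUE to curate without a null control"
      ))
    }
    return(list(curated = hits, removed = character()))
  }
  null_tab <- arm_sums(psm, null_ids)
  null_total <- null_tab$total[match(hits, null_tab$protein_id)]
  null_total[is.na(null_total)] <- 0
  removed <- hits[null_total >= null_min_count]
  list(curated = setdiff(hits, removed), removed = removed)
}

#' Reconcile hit sets across the two copper conditions
#'
#' The union of the per-condition hit sets is the interactome; the
#' intersection — proteins recovered regardless of copper status — is the
#' core of stable and/or strong interactors.
#'
#' @param hits_bcs,hits_cu Character vectors of curated hits per condition.
#' @return List with sorted character vectors `interactome`, `core`,
#'   `bcs_only`, `cu_only`.
#' @export
reconcile_conditions <- function(hits_bcs, hits_cu) {
  srt <- function(x) sort(unique(x), method = "radix")
  list(
    interactome = srt(union(hits_bcs, hits_cu)),
    core = srt(intersect(hits_bcs, hits_cu)),
    bcs_only = srt(setdiff(hits_bcs, hits_cu)),
    cu_only = srt(setdiff(hits_cu, hits_bcs))
  )
}

#' Overlap of an interactome with a contaminant compendium
#'
#' Reports which interactors also appear on a contaminant list (e.g. a
#' CRAPome-style bead proteome) and the overlap as a percentage of the
#' interactome, rounded half-up to one decimal. Flagged proteins are
#' annotated, not removed: the comparison is a quality check on the
#' curation, since a specific interactome should share little with what
#' sticks to beads alone.
#'
#' @param interactome Character vector of curated interactors.
#' @param contaminants Character vector of contaminant identifiers.
#' @return List with sorted character vector `overlap` and numeric
#'   `percent` (0 with a warning when the interactome is empty).
#' @export
#' @examples
#' # the desk check: 31 of 541 interactors on a 335-protein bead proteome
#' ia <- sprintf("P%03d", 1:541)
#' cont <- c(ia[1:31], sprintf("C%03d", 1:304))
#' contaminant_overlap(ia, cont)$percent  # 5.7
contaminant_overlap <- function(interactome, contaminants) {
  overlap <- sort(intersect(interactome, contaminants), method = "radix")
  if (length(interactome) == 0) {
    warning("empty interactome: contaminant overlap reported as 0")
    return(list(overlap = character(), percent = 0))
  }
  list(
    overlap = overlap,
    percent = round_half_up(100 * length(overlap) / length(interactome), 1)
  )
}

#' Curate an AP-MS interactome from PSM counts and controls
#'
#' Runs the full curation path: per-condition ratio filtering against the
#' peptide-competition control ([call_hits()]), elimination of proteins
#' recovered from bait-null cells ([subtract_null()]), reconciliation of
#' the BCS and CU hit sets into interactome and core
#' ([reconcile_conditions()]), and the contaminant-list audit
#' ([contaminant_overlap()]). The bait is scored like any protein and
#' reported in `$bait`, but excluded from the interactome and the per-
#' condition hit sets — it is the bait, not a prey.
#'
#' @param psm PSM tibble or path to a PSM TSV.
#' @param design Design tibble or path to a design YAML.
#' @param contaminants Character vector of contaminant identifiers or path
#'   to a contaminant list; may be empty.
#' @param bait_id Bait protein identifier, or `NULL` if the bait is not in
#'   the table under a known identifier.
#' @param conditions The two conditions to reconcile.
#' @param drop_contaminants Remove contaminant-listed proteins from the
#'   reported sets instead of merely annotating them.
#' @inheritParams call_hits
#' @inheritParams subtract_null
#' @return An object of class `curated_interactome`: list with
#'   `hits_bcs`, `hits_cu` (curated per-condition sets), `interactome`,
#'   `core`, `bcs_only`, `cu_only`, `null_removed`, `contaminant_overlap`,
#'   `overlap_percent`, per-condition ratio `records`, `bait` (the bait's
#'   records and whether it passed), and `params`.
#' @export
curate_interactome <- function(psm, design, contaminants = character(),
                               bait_id = NULL,
                               conditions = c("BCS", "CU"),
                               threshold = 2, pseudocount = 0.5,
                               min_count = 2, null_min_count = 2,
                               ge = FALSE, drop_contaminants = FALSE,
                               allow_missing_null = FALSE) {
  if (is.character(psm) && length(psm) == 1) psm <- read_psm_table(psm)
  if (is.character(design) && length(design) == 1) design <- read_design(design)
  if (is.character(contaminants) && length(contaminants) == 1 &&
      file.exists(contaminants)) {
    contaminants <- read_contaminant_list(contaminants)
  }
  stopifnot(length(conditions) == 2)

  records <- lapply(conditions, function(cond) {
    call_hits(psm, design, cond, threshold = threshold,
              pseudocount = pseudocount, min_count = min_count, ge = ge)
  })
  names(records) <- conditions

  curated <- lapply(records, function(rec) {
    subtract_null(rec$protein_id[rec$pass], psm, design,
                  null_min_count = null_min_count,
                  allow_missing_null = allow_missing_null)
  })
  null_removed <- sort(unique(unlist(lapply(curated, `[[`, "removed"))),
                       method = "radix")

  hits <- lapply(curated, `[[`, "curated")
  bait_info <- NULL
  if (!is.null(bait_id)) {
    bait_info <- list(
      protein_id = bait_id,
      records = dplyr::bind_rows(lapply(conditions, function(cond) {
        rec <- records[[cond]]
        row <- rec[rec$protein_id == bait_id, , drop = FALSE]
        if (nrow(row)) row$condition <- cond
        row
      })),
      null_removed = bait_id %in% null_removed
    )
    hits <- lapply(hits, setdiff, y = bait_id)
  }

  parts <- reconcile_conditions(hits[[1]], hits[[2]])
  cont <- contaminant_overlap(
    parts$interactome,
    if (length(parts$interactome)) contaminants else character()
  )

  if (drop_contaminants && length(cont$overlap)) {
    hits <- lapply(hits, setdiff, y = cont$overlap)
    parts <- reconcile_conditions(hits[[1]], hits[[2]])
  }

  structure(
    list(
      hits_bcs = sort(hits[[1]], method = "radix"),
      hits_cu = sort(hits[[2]], method = "radix"),
      interactome = parts$interactome,
      core = parts$core,
      bcs_only = parts$bcs_only,
      cu_only = parts$cu_only,
      null_removed = null_removed,
      contaminant_overlap = cont$overlap,
      overlap_percent = cont$percent,
      records = records,
      bait = bait_info,
      params = list(
        conditions = conditions, threshold = threshold,
        pseudocount = pseudocount, min_count = min_count,
        null_min_count = null_min_count, ge = ge,
        drop_contaminants = drop_contaminants,
        bait_id = bait_id
      )
    ),
    class = "curated_interactome"
  )
}

#' @export
print.curated_interactome <- function(x, ...) {
  cat("Curated AP-MS interactome\n")
  cat(sprintf("  hits (BCS): %d   hits (CU): %d\n",
              length(x$hits_bcs), length(x$hits_cu)))
  cat(sprintf("  interactome: %d   core (both conditions): %d\n",
              length(x$interactome), length(x$core)))
  cat(sprintf("  removed by bait-null control: %d\n", length(x$null_removed)))
  cat(sprintf("  contaminant-list overlap: %d (%.1f%%)\n",
              length(x$contaminant_overlap), x$overlap_percent))
  invisible(x)
}

#' Tabulate a curated interactome
#'
#' Flattens a [curate_interactome()] result into one row per interactor
#' with its per-condition ratios and flags, the layout written to
#' `interactome.tsv` by [run_all()].
#'
#' @param curated A `curated_interactome`.
#' @return A tibble with columns `protein_id`, `gene_symbol`, `ratio_bcs`,
#'   `ratio_cu`, `in_core`, `contaminant_flag`, `null_removed_flag`.
#' @export
interactome_table <- function(curated) {
  stopifnot(inherits(curated, "curated_interactome"))
  ids <- curated$interactome
  conds <- curated$params$conditions
  get_ratio <- function(cond) {
    rec <- curated$records[[cond]]
    rec$ratio[match(ids, rec$protein_id)]
  }
  symbols <- curated$records[[conds[1]]]$gene_symbol[
    match(ids, curated$records[[conds[1]]]$protein_id)]
  sym2 <- curated$records[[conds[2]]]$gene_symbol[
    match(ids, curated$records[[conds[2]]]$protein_id)]
  symbols[is.na(symbols) | symbols == ""] <- sym2[is.na(symbols) | symbols == ""]
  tibble::tibble(
    protein_id = ids,
    gene_symbol = ifelse(is.na(symbols), "", symbols),
    ratio_bcs = get_ratio(conds[1]),
    ratio_cu = get_ratio(conds[2]),
    in_core = ids %in% curated$core,
    contaminant_flag = ids %in% curated$contaminant_overlap,
    null_removed_flag = FALSE  # members are post-subtraction by construction
  )
}
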