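#' Configuration for a simulated peptide-competition AP-MS experiment
#'
#' Builds and validates the parameter set for [generate_experiment()].
#' The simulated design mirrors a four-arm immunoprecipitation: wild-type
#' cells under a copper-chelated (BCS) and a copper-loaded (CU) condition,
#' each immunoprecipitated with and without an excess of competing
#' antigenic peptide, plus a single bait-null isolation that contains only
#' bead background.
#'
#' Spectral counts are drawn from a negative-binomial distribution
#' parameterised by mean and `dispersion` (the `size` parameter; the
#' Poisson limit is recovered as `dispersion` grows). True preys have mean
#' `mu_true` in the minus-peptide arm(s) of the condition(s) they belong
#' to, `mu_true * suppression` in the matching plus-peptide arm(s), and a
#' small leak mean `null_leak * mu_background` everywhere else, including
#' the bait-null arm (set `null_leak = 0` for a structurally clean null).
#' Background proteins have mean `mu_background` in every arm. The bait is
#' assigned fixed (not sampled) counts so bait-detection behaviour is
#' deterministic.
#'
#' @param n_true Number of true bait preys.
#' @param n_background Number of bead-background proteins.
#' @param frac_shared Fraction of true preys interacting under both copper
#'   conditions; the rest are split evenly between BCS-only and CU-only,
#'   with the odd remainder going to BCS-only.
#' @param mu_true Mean PSM count of a true prey in a minus-peptide IP of
#'   its condition.
#' @param mu_background Mean PSM count of a background protein in any arm.
#' @param suppression Factor in (0, 1] multiplying a true prey's mean in
#'   the plus-peptide arm; 1 means the competing peptide has no effect.
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param frac_contaminant Fraction of background proteins placed on the
#'   simulated contaminant list.
#' @param bait_psm Fixed PSM count of the bait in wild-type minus-peptide
#'   arms; the plus-peptide arms receive `round(bait_psm * suppression)`.
#' @param null_leak Mean of a true prey outside its condition and in the
#'   bait-null arm, as a fraction of `mu_background`; must lie in
#'   \[0, 0.1\]. The default 0.025 keeps the null isolation nearly free of
#'   bait-dependent signal, as expected of a genetic null, while still
#'   exercising null subtraction.
#' @param n_rep Replicate IPs per wild-type arm; the bait-null arm is
#'   always a single isolation.
#' @param bait_id Identifier used for the bait protein.
#' @param seed Integer seed; per-arm substreams are derived as
#'   `seed + offset` with fixed offsets (membership/contaminant draw 0,
#'   WT/BCS/minus 1, WT/BCS/plus 2, WT/CU/minus 3, WT/CU/plus 4, null 5),
#'   so adding arms never reshuffles existing draws.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [generate_experiment()], [evaluate_recovery()]
#' @export
#' @examples
#' cfg <- sim_config(n_true = 20, n_background = 50, seed = 1)
#' exp <- generate_experiment(cfg)
#' head(exp$psm)
sim_config <- function(n_true = 150, n_background = 800, frac_shared = 0.5,
                       mu_true = 25, mu_background = 8, suppression = 0.1,
                       dispersion = 5, frac_contaminant = 0.4,
                       bait_psm = 100, null_leak = 0.025, n_rep = 1,
                       bait_id = "BAIT", seed = 1) {
  check_number(n_true, "n_true", min = 0, integer = TRUE)
  check_number(n_background, "n_background", min = 0, integer = TRUE)
  check_number(frac_shared, "frac_shared", min = 0, max = 1)
  check_number(mu_true, "mu_true", min = 0)
  check_number(mu_background, "mu_background", min = 0)
  check_number(suppression, "suppression", min = 0, max = 1, strict_min = TRUE)
  check_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  check_number(frac_contaminant, "frac_contaminant", min = 0, max = 1)
  check_number(bait_psm, "bait_psm", min = 0, integer = TRUE)
  check_number(null_leak, "null_leak", min = 0, max = 0.1)
  check_number(n_rep, "n_rep", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (!is.character(bait_id) || length(bait_id) != 1L || !nzchar(bait_id)) {
    abort_config("field 'bait_id' must be a nonempty string")
  }
  structure(
    list(
      n_true = as.integer(n_true), n_background = as.integer(n_background),
      frac_shared = frac_shared, mu_true = mu_true,
      mu_background = mu_background, suppression = suppression,
      dispersion = dispersion, frac_contaminant = frac_contaminant,
      bait_psm = as.integer(bait_psm), null_leak = null_leak,
      n_rep = as.integer(n_rep), bait_id = bait_id, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Fixed substream offsets; see ?sim_config.
.arm_offsets <- c(
  structure_draw = 0L,
  WT_BCS_minus = 1L, WT_BCS_plus = 2L,
  WT_CU_minus = 3L, WT_CU_plus = 4L,
  NULL_minus = 5L
)

#' Generate a ground-truthed simulated AP-MS experiment
#'
#' Draws a long-form PSM count table for the five arms of the simulated
#' peptide-competition design (see [sim_config()]) together with the
#' sample-to-arm design table and a per-protein truth table. Output is a
#' deterministic function of the configuration, including its seed. Rows
#' with a zero count are omitted from the PSM table, as in real search
#' output where unobserved proteins simply do not appear.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `apms_experiment` with elements
#'   \describe{
#'     \item{psm}{tibble with columns `protein_id`, `gene_symbol`, `psm`,
#'       `sample_id` (zero-count rows dropped).}
#'     \item{design}{tibble with columns `sample_id`, `genotype`
#'       (`WT`/`NULL`), `condition` (`BCS`/`CU`/`NA`), `peptide`
#'       (`plus`/`minus`).}
#'     \item{truth}{tibble with columns `protein_id`, `label`
#'       (`true_prey`/`background`/`bait`), `condition_membership`
#'       (`BCS_only`/`Cu_only`/`both`/`n/a`), `contaminant` (logical).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  cfg <- config

  prey_ids <- if (cfg$n_true > 0) sprintf("TP%04d", seq_len(cfg$n_true)) else character()
  bg_ids <- if (cfg$n_background > 0) sprintf("BG%04d", seq_len(cfg$n_background)) else character()

  # Condition membership is positional (no RNG): shared preys first, then
  # BCS-only (takes the odd remainder), then CU-only.
  n_shared <- round(cfg$frac_shared * cfg$n_true)
  n_private <- cfg$n_true - n_shared
  n_bcs_only <- ceiling(n_private / 2)
  membership <- rep("Cu_only", cfg$n_true)
  if (n_shared > 0) membership[seq_len(n_shared)] <- "both"
  if (n_bcs_only > 0) membership[n_shared + seq_len(n_bcs_only)] <- "BCS_only"

  # Contaminant flags are a seeded random subset of the background.
  n_cont <- round(cfg$frac_contaminant * cfg$n_background)
  cont_ids <- with_seed(cfg$seed + .arm_offsets[["structure_draw"]], {
    sample(bg_ids, n_cont)
  })

  truth <- tibble::tibble(
    protein_id = c(cfg$bait_id, prey_ids, bg_ids),
    label = c("bait", rep("true_prey", cfg$n_true),
              rep("background", cfg$n_background)),
    condition_membership = c("n/a", membership, rep("n/a", cfg$n_background)),
    contaminant = c(FALSE, rep(FALSE, cfg$n_true),
                    bg_ids %in% cont_ids)
  )

  wt_arms <- expand.grid(
    condition = c("BCS", "CU"), peptide = c("minus", "plus"),
    rep = seq_len(cfg$n_rep), stringsAsFactors = FALSE
  )
  design <- tibble::tibble(
    sample_id = c(
      sprintf("WT_%s_%s_%d", wt_arms$condition, wt_arms$peptide, wt_arms$rep),
      "NULL_minus_1"
    ),
    genotype = c(rep("WT", nrow(wt_arms)), "NULL"),
    condition = c(wt_arms$condition, "NA"),
    peptide = c(wt_arms$peptide, "minus")
  )

  leak <- cfg$null_leak * cfg$mu_background
  prey_mean <- function(member, condition, peptide) {
    in_cond <- member == "both" |
      (member == "BCS_only" & condition == "BCS") |
      (member == "Cu_only" & condition == "CU")
    ifelse(in_cond,
           if (peptide == "minus") cfg$mu_true else cfg$mu_true * cfg$suppression,
           leak)
  }

  arm_key <- function(genotype, condition, peptide) {
    if (genotype == "NULL") "NULL_minus" else paste("WT", condition, peptide, sep = "_")
  }

  non_bait <- c(prey_ids, bg_ids)
  rows <- vector("list", nrow(design))
  i <- 0L
  for (arm in c("WT_BCS_minus", "WT_BCS_plus", "WT_CU_minus", "WT_CU_plus",
                "NULL_minus")) {
    arm_samples <- design$sample_id[
      vapply(seq_len(nrow(design)), function(j) {
        arm_key(design$genotype[j], design$condition[j], design$peptide[j])
      }, character(1)) == arm
    ]
    is_null_arm <- arm == "NULL_minus"
    parts <- strsplit(arm, "_")[[1]]
    condition <- if (is_null_arm) "NA" else parts[2]
    peptide <- if (is_null_arm) "minus" else parts[3]

    means <- c(
      if (is_null_arm) rep(leak, cfg$n_true)
      else prey_mean(membership, condition, peptide),
      rep(cfg$mu_background, cfg$n_background)
    )
    counts <- with_seed(cfg$seed + .arm_offsets[[arm]], {
      lapply(arm_samples, function(s) {
        stats::rnbinom(length(non_bait), size = cfg$dispersion, mu = means)
      })
    })
    bait_count <- if (is_null_arm) 0L
      else if (peptide == "minus") cfg$bait_psm
      else as.integer(round(cfg$bait_psm * cfg$suppression))
    for (j in seq_along(arm_samples)) {
      i <- i + 1L
      rows[[i]] <- tibble::tibble(
        protein_id = c(cfg$bait_id, non_bait),
        psm = c(bait_count, counts[[j]]),
        sample_id = arm_samples[j]
      )
    }
  }

  long <- dplyr::bind_rows(rows[seq_len(i)])
  long <- long[long$psm > 0L, , drop = FALSE]
  psm <- tibble::tibble(
    protein_id = long$protein_id,
    gene_symbol = long$protein_id,
    psm = as.integer(long$psm),
    sample_id = long$sample_id
  )

  structure(
    list(psm = psm, design = design, truth = truth, config = cfg),
    class = "apms_experiment"
  )
}

#' @export
print.apms_experiment <- function(x, ...) {
  cat(sprintf(
    "Simulated AP-MS experiment: %d proteins (%d true preys, %d background), %d samples, %d PSM rows\n",
    nrow(x$truth), sum(x$truth$label == "true_prey"),
    sum(x$truth$label == "background"), nrow(x$design), nrow(x$psm)
  ))
  invisible(x)
}

#' Benchmark a curated interactome against simulation ground truth
#'
#' Compares a curated hit set with the true-prey labels of a simulated
#' experiment and reports recall, precision, and per-condition confusion
#' counts. Undefined ratios (division by zero) are reported as `NA`, never
#' as 0.
#'
#' @param curated A [curate_interactome()] result, or a character vector of
#'   curated protein identifiers.
#' @param truth Truth tibble from [generate_experiment()].
#' @return A list of class `recovery_report` with `recall`, `precision`,
#'   `n_true`, `n_curated`, and a `conditions` tibble of per-condition
#'   true-positive / false-positive / false-negative counts.
#' @export
evaluate_recovery <- function(curated, truth) {
  per_condition <- NULL
  if (inherits(curated, "curated_interactome")) {
    per_condition <- list(BCS = curated$hits_bcs, CU = curated$hits_cu)
    curated <- curated$interactome
  }
  stopifnot(is.character(curated))
  if (length(curated) > 0 && !any(curated %in% truth$protein_id)) {
    abort_value("curated identifiers share no member with the truth table (disjoint namespaces?)")
  }

  true_prey <- truth$protein_id[truth$label == "true_prey"]
  tp <- length(intersect(curated, true_prey))
  recall <- if (length(true_prey) == 0) NA_real_ else tp / length(true_prey)
  precision <- if (length(curated) == 0) NA_real_ else tp / length(curated)

  conditions <- NULL
  if (!is.null(per_condition)) {
    conditions <- dplyr::bind_rows(lapply(names(per_condition), function(cond) {
      member <- switch(cond,
        BCS = c("both", "BCS_only"),
        CU = c("both", "Cu_only")
      )
      cond_true <- truth$protein_id[truth$label == "true_prey" &
                                      truth$condition_membership %in% member]
      hits <- per_condition[[cond]]
      tibble::tibble(
        condition = cond,
        tp = length(intersect(hits, cond_true)),
        fp = length(setdiff(hits, cond_true)),
        fn = length(setdiff(cond_true, hits))
      )
    }))
  }

  structure(
    list(recall = recall, precision = precision,
         n_true = length(true_prey), n_curated = length(curated),
         conditions = conditions),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat(sprintf("Recovery: recall %s, precision %s (%d true preys, %d curated)\n",
              fmt(x$recall), fmt(x$precision), x$n_true, x$n_curated))
  if (!is.null(x$conditions)) print(x$conditions)
  invisible(x)
}
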