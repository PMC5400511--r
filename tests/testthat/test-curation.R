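test_that("enrichment ratio implements the calling rule and its edge cases", {
  r <- enrichment_ratio(10, 4, pseudocount = 0)
  expect_equal(r$ratio, 2.5)
  expect_true(r$pass)

  # exactly 2-fold fails the strict test, passes with ge
  r <- enrichment_ratio(6, 3, pseudocount = 0)
  expect_equal(r$ratio, 2)
  expect_false(r$pass)
  expect_true(enrichment_ratio(6, 3, pseudocount = 0, ge = TRUE)$pass)

  # zero in the competition control: auto-pass at min_count
  r <- enrichment_ratio(5, 0, min_count = 2)
  expect_identical(r$ratio, Inf)
  expect_true(r$pass)

  # below min_count the pseudocount takes over
  r <- enrichment_ratio(1, 0, pseudocount = 0.5, min_count = 2)
  expect_equal(r$ratio, 3)
  expect_true(r$pass)

  expect_error(enrichment_ratio(-1, 0), class = "apms_value_error")
  expect_error(enrichment_ratio(3, -2), class = "apms_value_error")
})

test_that("call_hits sums replicates and records only minus-arm proteins", {
  design <- toy_design()
  design <- dplyr::bind_rows(design, tibble::tibble(
    sample_id = "WT_BCS_minus_2", genotype = "WT",
    condition = "BCS", peptide = "minus"
  ))
  psm <- toy_psm(list(
    X = c(WT_BCS_minus_1 = 12, WT_BCS_minus_2 = 8, WT_BCS_plus_1 = 2),
    Y = c(WT_BCS_minus_1 = 5, WT_BCS_plus_1 = 5),
    Z = c(WT_BCS_plus_1 = 9)  # never seen without competitor
  ))
  rec <- call_hits(psm, design, "BCS")
  expect_setequal(rec$protein_id, c("X", "Y"))  # Z gets no record
  expect_equal(rec$a[rec$protein_id == "X"], 20)
  expect_true(rec$pass[rec$protein_id == "X"])
  expect_false(rec$pass[rec$protein_id == "Y"])

  # design rows for the condition's arms must exist
  expect_error(call_hits(psm, toy_design()[1:2, ], "CU"), "CU",
               class = "apms_config_error")
  only_minus <- toy_design()[c(1, 3, 5), ]
  expect_error(call_hits(psm, only_minus, "BCS"),
               class = "apms_config_error")
})

test_that("null subtraction removes hits at the evidence threshold only", {
  design <- toy_design()
  psm <- toy_psm(list(
    A = c(WT_BCS_minus_1 = 10, NULL_minus_1 = 1),
    B = c(WT_BCS_minus_1 = 10, NULL_minus_1 = 5),
    C = c(WT_BCS_minus_1 = 10)
  ))
  out <- subtract_null(c("A", "B", "C"), psm, design)
  expect_setequal(out$curated, c("A", "C"))  # A retained: 1 < null_min_count
  expect_setequal(out$removed, "B")
  expect_length(intersect(out$curated, out$removed), 0)

  out1 <- subtract_null(c("A", "B", "C"), psm, design, null_min_count = 1)
  expect_setequal(out1$removed, c("A", "B"))

  no_null <- design[design$genotype == "WT", ]
  expect_error(subtract_null("A", psm, no_null), class = "apms_config_error")
  out2 <- subtract_null(c("A", "B"), psm, no_null, allow_missing_null = TRUE)
  expect_setequal(out2$curated, c("A", "B"))
})

test_that("condition reconciliation partitions the interactome", {
  r <- reconcile_conditions(c("A", "B"), c("B", "C"))
  expect_equal(r$interactome, c("A", "B", "C"))
  expect_equal(r$core, "B")
  expect_equal(r$bcs_only, "A")
  expect_equal(r$cu_only, "C")
  expect_equal(length(r$bcs_only) + length(r$cu_only) + length(r$core),
               length(r$interactome))

  same <- reconcile_conditions(c("A", "B"), c("B", "A"))
  expect_equal(same$core, same$interactome)
})

test_that("contaminant overlap reports a half-up one-decimal percentage", {
  ia <- sprintf("P%03d", 1:541)
  cont <- c(ia[1:31], sprintf("CONT%03d", 1:304))  # 335 total, 31 shared
  ov <- contaminant_overlap(ia, cont)
  expect_length(ov$overlap, 31)
  expect_identical(ov$percent, 5.7)

  expect_equal(contaminant_overlap(ia, character())$percent, 0)
  expect_equal(contaminant_overlap(c("A", "B"), c("A", "B", "C"))$percent, 100)
  # 1/8 = 12.5% must not round half-to-even to 12.4 or truncate
  expect_equal(contaminant_overlap(sprintf("x%d", 1:8), "x1")$percent, 12.5)
  expect_warning(empty <- contaminant_overlap(character(), c("A")), "empty")
  expect_equal(empty$percent, 0)
})

test_that("curation matches the straight-line oracle on small simulations", {
  for (seed in c(1, 7, 13, 21, 34)) {
    exp <- generate_experiment(small_sim_config(seed))
    expect_lte(nrow(exp$truth), 50)
    cur <- curate_interactome(exp$psm, exp$design, character(), bait_id = "BAIT")
    orc <- oracle_curate(exp$psm, exp$design, bait_id = "BAIT")
    expect_identical(cur$hits_bcs, orc$hits_bcs)
    expect_identical(cur$hits_cu, orc$hits_cu)
    expect_identical(cur$interactome, orc$interactome)
    expect_identical(cur$core, orc$core)
  }
})

test_that("curation matches the oracle under non-default parameters", {
  exp <- generate_experiment(small_sim_config(99, suppression = 0.3, n_rep = 2))
  for (params in list(
    list(threshold = 3, pseudocount = 1, min_count = 3, null_min_count = 1),
    list(threshold = 2, pseudocount = 0, min_count = 2, null_min_count = 2)
  )) {
    cur <- do.call(curate_interactome, c(
      list(exp$psm, exp$design, character(), bait_id = "BAIT"), params
    ))
    orc <- do.call(oracle_curate, c(
      list(exp$psm, exp$design, bait_id = "BAIT"), params
    ))
    expect_identical(cur$interactome, orc$interactome)
    expect_identical(cur$core, orc$core)
  }
})

test_that("curated sets satisfy their algebra and the bait is excluded", {
  exp <- generate_experiment(sim_config(n_true = 40, n_background = 120, seed = 4))
  cont <- exp$truth$protein_id[exp$truth$contaminant]
  cur <- curate_interactome(exp$psm, exp$design, cont, bait_id = "BAIT")

  expect_true(all(cur$core %in% cur$interactome))
  expect_true(all(cur$core %in% cur$hits_bcs))
  expect_true(all(cur$core %in% cur$hits_cu))
  expect_setequal(union(cur$hits_bcs, cur$hits_cu), cur$interactome)
  expect_length(intersect(cur$interactome, cur$null_removed), 0)
  expect_true(all(cur$contaminant_overlap %in% cur$interactome))
  expect_lt(
    abs(cur$overlap_percent -
          100 * length(cur$contaminant_overlap) / length(cur$interactome)),
    0.05 + 1e-9  # one-decimal rounding of the exact percentage
  )

  # the bait passes the filter (high fixed counts) yet is not a prey
  expect_true(any(cur$bait$records$pass))
  expect_false("BAIT" %in% cur$interactome)

  # dropping contaminants removes exactly the flagged members
  dropped <- curate_interactome(exp$psm, exp$design, cont, bait_id = "BAIT",
                                drop_contaminants = TRUE)
  expect_setequal(dropped$interactome,
                  setdiff(cur$interactome, cur$contaminant_overlap))
})

test_that("interactome_table carries ratios and flags for every member", {
  exp <- generate_experiment(sim_config(n_true = 25, n_background = 60, seed = 6))
  cur <- curate_interactome(exp$psm, exp$design,
                            exp$truth$protein_id[exp$truth$contaminant],
                            bait_id = "BAIT")
  tab <- interactome_table(cur)
  expect_equal(tab$protein_id, cur$interactome)
  expect_equal(tab$in_core, tab$protein_id %in% cur$core)
  expect_equal(tab$contaminant_flag, tab$protein_id %in% cur$contaminant_overlap)
  # a core member has a finite or infinite pass ratio in both conditions
  core_rows <- tab[tab$in_core, ]
  expect_true(all(core_rows$ratio_bcs > 2 | is.infinite(core_rows$ratio_bcs)))
  expect_true(all(core_rows$ratio_cu > 2 | is.infinite(core_rows$ratio_cu)))
})
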