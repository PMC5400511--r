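test_that("generation is deterministic under a fixed seed", {
  e1 <- generate_experiment(sim_config(n_true = 20, n_background = 60, seed = 7))
  e2 <- generate_experiment(sim_config(n_true = 20, n_background = 60, seed = 7))
  expect_identical(e1$psm, e2$psm)
  expect_identical(e1$design, e2$design)
  expect_identical(e1$truth, e2$truth)
  e3 <- generate_experiment(sim_config(n_true = 20, n_background = 60, seed = 8))
  expect_false(identical(e1$psm, e3$psm))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_experiment(sim_config(n_true = 5, n_background = 10, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("truth table partitions the protein universe", {
  cfg <- sim_config(n_true = 21, n_background = 40, frac_shared = 0.4,
                    frac_contaminant = 0.25, seed = 3)
  truth <- generate_experiment(cfg)$truth
  expect_equal(nrow(truth), 1 + 21 + 40)
  expect_false(anyDuplicated(truth$protein_id) > 0)
  expect_equal(sum(truth$label == "bait"), 1L)
  # contaminant flags only on background, count = round(frac * n_background)
  expect_true(all(truth$label[truth$contaminant] == "background"))
  expect_equal(sum(truth$contaminant), round(0.25 * 40))
  # shared fraction and the even private split, remainder to BCS-only
  n_shared <- round(0.4 * 21)
  expect_equal(sum(truth$condition_membership == "both"), n_shared)
  expect_equal(sum(truth$condition_membership == "BCS_only"),
               ceiling((21 - n_shared) / 2))
  expect_equal(sum(truth$condition_membership == "Cu_only"),
               floor((21 - n_shared) / 2))
})

test_that("n_true = 0 yields only background and the bait", {
  truth <- generate_experiment(sim_config(n_true = 0, n_background = 15, seed = 1))$truth
  expect_setequal(unique(truth$label), c("bait", "background"))
  expect_true(all(truth$label[truth$protein_id != "BAIT"] == "background"))
})

test_that("arm means follow the design: signal, suppression, leak, fixed bait", {
  cfg <- sim_config(n_true = 200, n_background = 200, frac_shared = 1,
                    mu_true = 40, mu_background = 8, suppression = 0.2,
                    dispersion = 50, null_leak = 0.025, seed = 11)
  exp <- generate_experiment(cfg)
  full <- merge(expand.grid(protein_id = exp$truth$protein_id,
                            sample_id = exp$design$sample_id,
                            stringsAsFactors = FALSE),
                exp$psm[, c("protein_id", "sample_id", "psm")],
                all.x = TRUE)
  full$psm[is.na(full$psm)] <- 0
  mean_of <- function(label, sample) {
    ids <- exp$truth$protein_id[exp$truth$label == label]
    mean(full$psm[full$protein_id %in% ids & full$sample_id == sample])
  }
  # sampling error at n = 200, dispersion 50: sd of the mean ~ mu/15
  expect_equal(mean_of("true_prey", "WT_BCS_minus_1"), 40, tolerance = 0.15)
  expect_equal(mean_of("true_prey", "WT_BCS_plus_1"), 8, tolerance = 0.2)
  expect_equal(mean_of("background", "NULL_minus_1"), 8, tolerance = 0.2)
  expect_lt(mean_of("true_prey", "NULL_minus_1"), 8 / 10)
  # bait counts are fixed, not sampled
  bait <- full[full$protein_id == "BAIT", ]
  expect_equal(bait$psm[bait$sample_id == "WT_BCS_minus_1"], 100)
  expect_equal(bait$psm[bait$sample_id == "WT_CU_minus_1"], 100)
  expect_equal(bait$psm[bait$sample_id == "WT_BCS_plus_1"], round(100 * 0.2))
  expect_equal(bait$psm[bait$sample_id == "NULL_minus_1"], 0)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(suppression = 0), "suppression",
               class = "apms_config_error")
  expect_error(sim_config(dispersion = -1), "dispersion",
               class = "apms_config_error")
  expect_error(sim_config(frac_shared = 1.5), "frac_shared",
               class = "apms_config_error")
  expect_error(sim_config(n_true = -3), "n_true",
               class = "apms_config_error")
  expect_error(sim_config(null_leak = 0.5), "null_leak",
               class = "apms_config_error")
})

test_that("recovery report computes recall/precision with undefined ratios as NA", {
  exp <- generate_experiment(sim_config(n_true = 10, n_background = 20, seed = 2))
  tp <- exp$truth$protein_id[exp$truth$label == "true_prey"]

  perfect <- evaluate_recovery(tp, exp$truth)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)

  empty <- evaluate_recovery(character(), exp$truth)
  expect_equal(empty$recall, 0)
  expect_true(is.na(empty$precision))

  half <- evaluate_recovery(c(tp[1:5], "BG0001", "BG0002"), exp$truth)
  expect_equal(half$recall, 0.5)
  expect_equal(half$precision, 5 / 7)

  expect_error(evaluate_recovery(c("XX1", "XX2"), exp$truth),
               "disjoint", class = "apms_value_error")
})

test_that("per-condition confusion counts respect condition membership", {
  exp <- generate_experiment(sim_config(seed = 7))
  cur <- curate_interactome(exp$psm, exp$design, character(), bait_id = "BAIT")
  rec <- evaluate_recovery(cur, exp$truth)
  expect_named(rec$conditions, c("condition", "tp", "fp", "fn"))
  bcs_true <- sum(exp$truth$condition_membership %in% c("both", "BCS_only"))
  row <- rec$conditions[rec$conditions$condition == "BCS", ]
  expect_equal(row$tp + row$fn, bcs_true)
  expect_equal(row$tp + row$fp, length(cur$hits_bcs))
})
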