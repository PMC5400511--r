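# Small in-code fixtures shared across test files.

# Five-sample design: one WT replicate per (condition, peptide) arm plus
# the bait-null isolation.
toy_design <- function() {
  tibble::tibble(
    sample_id = c("WT_BCS_minus_1", "WT_BCS_plus_1",
                  "WT_CU_minus_1", "WT_CU_plus_1", "NULL_minus_1"),
    genotype = c("WT", "WT", "WT", "WT", "NULL"),
    condition = c("BCS", "BCS", "CU", "CU", "NA"),
    peptide = c("minus", "plus", "minus", "plus", "minus")
  )
}

# Long-form PSM tibble from a named list: counts[[protein]] is a named
# vector of sample_id -> psm.
toy_psm <- function(counts) {
  rows <- lapply(names(counts), function(p) {
    v <- counts[[p]]
    tibble::tibble(protein_id = p, gene_symbol = p,
                   psm = as.integer(v), sample_id = names(v))
  })
  dplyr::bind_rows(rows)
}

# Down-scaled simulation for oracle-equivalence sweeps (<= 50 proteins).
small_sim_config <- function(seed, ...) {
  sim_config(n_true = 12, n_background = 30, seed = seed, ...)
}
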