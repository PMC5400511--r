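# Independent oracles: deliberately plain, loop-based re-derivations of
# the contracts, sharing no code with the package internals.

# Re-apply the ratio / null-subtraction / reconciliation rules directly
# over the long-form table, one protein at a time.
oracle_curate <- function(psm, design, threshold = 2, pseudocount = 0.5,
                          min_count = 2, null_min_count = 2, bait_id = NULL) {
  hit_set <- function(cond) {
    minus <- design$sample_id[design$genotype == "WT" &
                                design$condition == cond & design$peptide == "minus"]
    plus <- design$sample_id[design$genotype == "WT" &
                               design$condition == cond & design$peptide == "plus"]
    prots <- unique(psm$protein_id[psm$sample_id %in% minus & psm$psm > 0])
    hits <- character()
    for (p in prots) {
      a <- sum(psm$psm[psm$protein_id == p & psm$sample_id %in% minus])
      b <- sum(psm$psm[psm$protein_id == p & psm$sample_id %in% plus])
      pass <- if (b == 0 && a >= min_count) {
        TRUE
      } else {
        (a + pseudocount) / (b + pseudocount) > threshold
      }
      if (pass) hits <- c(hits, p)
    }
    hits
  }
  null_ids <- design$sample_id[design$genotype == "NULL" & design$peptide == "minus"]
  drop_null <- function(h) {
    keep <- character()
    for (p in h) {
      nn <- sum(psm$psm[psm$protein_id == p & psm$sample_id %in% null_ids])
      if (nn < null_min_count) keep <- c(keep, p)
    }
    keep
  }
  hb <- drop_null(hit_set("BCS"))
  hc <- drop_null(hit_set("CU"))
  if (!is.null(bait_id)) {
    hb <- setdiff(hb, bait_id)
    hc <- setdiff(hc, bait_id)
  }
  list(
    hits_bcs = sort(hb), hits_cu = sort(hc),
    interactome = sort(union(hb, hc)), core = sort(intersect(hb, hc))
  )
}

# Upper-tail hypergeometric probability by direct combinatorial
# enumeration of the favourable draws.
oracle_hyper_p <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j
# on the sorted sequence, mapped back; O(m^2) double loop on purpose.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}
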