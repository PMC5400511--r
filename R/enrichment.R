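#' Upper-tail hypergeometric probability for over-representation
#'
#' Exact probability of drawing at least `k` members of a category of
#' size `K` when sampling `n` items without replacement from a universe
#' of size `N`: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed hits in the category.
#' @param K Universe members in the category.
#' @param n Sample (hit-list) size.
#' @param N Universe size.
#' @return The exact upper-tail probability (1 when `k = 0`). Vectorised.
#' @export
#' @examples
#' hypergeom_p(5, 5, 5, 10)  # 1 / choose(10, 5)
hypergeom_p <- function(k, K, n, N) {
  check_ora_params(k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_ora_params <- function(k, K, n, N) {
  if (any(N < 0) || any(K < 0) || any(K > N) || any(n < 0) || any(n > N) ||
      any(k < 0) || any(k > pmin(K, n))) {
    abort_value("require 0 <= K <= N, 0 <= n <= N and 0 <= k <= min(K, n)")
  }
  invisible(NULL)
}

#' Hypergeometric standardised deviation (z-score)
#'
#' Standardises the observed category count against the hypergeometric
#' null: `z = (k - nK/N) / sd`, with
#' `sd = sqrt(nK(N-K)(N-n) / (N^2 (N-1)))`. Defined as 0 when the null
#' variance is 0 (degenerate margins). Negative for depleted sets.
#'
#' @inheritParams hypergeom_p
#' @return The z-score. Vectorised.
#' @export
hypergeom_z <- function(k, K, n, N) {
  check_ora_params(k, K, n, N)
  ek <- n * K / N
  v <- n * K * (N - K) * (N - n) / (N^2 * pmax(N - 1, 1))
  z <- ifelse(v > 0, (k - ek) / sqrt(v), 0)
  ifelse(is.nan(z), 0, z)
}

#' Haldane-corrected odds ratio for a 2x2 enrichment table
#'
#' Odds ratio of the table (in set & hit, in set & not hit; out of set &
#' hit, out of set & not hit). When any cell is zero, the Haldane
#' correction `correction` is added to all four cells so the estimate
#' stays finite.
#'
#' @inheritParams hypergeom_p
#' @param correction Value added to every cell when any cell is zero.
#' @return The odds ratio. Vectorised.
#' @export
odds_ratio <- function(k, K, n, N, correction = 0.5) {
  check_ora_params(k, K, n, N)
  x11 <- k
  x12 <- n - k
  x21 <- K - k
  x22 <- N - K - n + k
  c0 <- ifelse(x11 == 0 | x12 == 0 | x21 == 0 | x22 == 0, correction, 0)
  ((x11 + c0) * (x22 + c0)) / ((x21 + c0) * (x12 + c0))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusts p-values by the step-up rule: on the sorted sequence,
#' `q_(i) = min over j >= i of p_(j) * m / j`, mapped back to the input
#' order and capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the input order, with `q >= p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort_value("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Combined enrichment score
#'
#' Ranking score `c = z * (-log10 p)` pairing the deviation z-score with
#' the significance of the exact test; 0 when `p = 1` or `z = 0`,
#' negative for depleted sets.
#'
#' @param p Exact test p-value in (0, 1].
#' @param z Standardised deviation, e.g. from [hypergeom_z()].
#' @param base Logarithm base (10 by default).
#' @return The combined score. Vectorised.
#' @export
combined_score <- function(p, z, base = 10) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort_value("p-values must lie in (0, 1]")
  }
  z * (-log(p, base = base))
}

#' Gene-set over-representation analysis of a hit list
#'
#' Tests each set of a collection for over-representation in `hits`
#' relative to `universe` with the exact upper-tail hypergeometric test.
#' Set membership and the hit/universe lists are matched case-insensitively
#' (all symbols are folded to upper case). Hits absent from the universe
#' are dropped with a message. Each set is first restricted to the
#' universe; sets whose restricted size falls outside
#' `[min_set, max_set]` are skipped. Benjamini-Hochberg adjustment is
#' applied across all tested sets.
#'
#' @param hits Character vector of hit symbols.
#' @param universe Character vector of background symbols (the test
#'   universe). For AP-MS hit lists the detected proteome — every protein
#'   quantified in any IP arm — is the standard choice, guarding against
#'   abundance bias; see [detected_universe()].
#' @param collection A [gene_set_collection()] (e.g. from [read_gmt()]).
#' @param min_set,max_set Bounds on the universe-restricted set size.
#' @return A tibble of class `enrichment_result` with columns `set_name`,
#'   `description`, `k`, `K`, `n`, `N`, `p`, `q`, `odds`, `z`, `combined`,
#'   sorted by `combined` descending, ties by `p` ascending then
#'   `set_name`.
#' @export
enrich <- function(hits, universe, collection, min_set = 3, max_set = 2000) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort_config("enrichment universe is empty")
  hits <- unique(toupper(hits))
  outside <- setdiff(hits, universe)
  if (length(outside) > 0) {
    message(sprintf("enrich: dropping %d hit(s) absent from the universe",
                    length(outside)))
    hits <- intersect(hits, universe)
  }

  N <- length(universe)
  n <- length(hits)
  restricted <- lapply(collection$sets, intersect, y = universe)
  keep <- lengths(restricted) >= min_set & lengths(restricted) <= max_set
  if (!any(keep)) {
    warning("no gene set within the size bounds after restriction to the universe")
    empty <- tibble::tibble(
      set_name = character(), description = character(),
      k = integer(), K = integer(), n = integer(), N = integer(),
      p = numeric(), q = numeric(), odds = numeric(), z = numeric(),
      combined = numeric()
    )
    class(empty) <- c("enrichment_result", class(empty))
    return(empty)
  }
  restricted <- restricted[keep]

  K <- unname(lengths(restricted))
  k <- unname(vapply(restricted, function(s) length(intersect(hits, s)), integer(1)))
  p <- hypergeom_p(k, K, n, N)
  res <- tibble::tibble(
    set_name = names(restricted),
    description = unname(collection$description[names(restricted)]),
    k = as.integer(k), K = as.integer(K), n = as.integer(n), N = as.integer(N),
    p = p,
    q = bh_adjust(p),
    odds = odds_ratio(k, K, n, N),
    z = hypergeom_z(k, K, n, N)
  )
  res$combined <- combined_score(res$p, res$z)
  res <- res[order(-res$combined, res$p, res$set_name, method = "radix"), ]
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Default ORA universe: the detected proteome within the collection
#'
#' The background every hit list is compared against: gene symbols of all
#' proteins quantified in any IP arm, intersected with the union of the
#' collection's members. Restricting to detectable-and-annotated symbols
#' guards the test against abundance and annotation bias.
#'
#' @param psm PSM tibble.
#' @param collection A `gene_set_collection`.
#' @return Character vector of upper-cased symbols.
#' @export
detected_universe <- function(psm, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  detected <- unique(toupper(psm$gene_symbol[nzchar(psm$gene_symbol)]))
  members <- unique(toupper(unlist(collection$sets, use.names = FALSE)))
  intersect(detected, members)
}
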