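## De novo mutation candidate detection and the exact binomial
## enrichment test, computed in log space so that extreme tails (the
## worked study example is ~1e-67) keep at least three significant
## digits.

#' De novo candidate filter thresholds
#'
#' Conservative defaults: child genotype quality >= 20, depth >= 10 in
#' every trio member, no parental alt-supporting reads, and population
#' allele frequency below 1%.
#'
#' @param min_child_gq minimum child genotype quality.
#' @param min_depth minimum read depth per trio member.
#' @param max_parent_alt_reads maximum alt-supporting reads in either
#'   parent.
#' @param max_pop_af maximum population allele frequency.
#' @return list of class `denovo_filter_config`.
#' @export
denovo_filter_config <- function(min_child_gq = 20, min_depth = 10,
                                 max_parent_alt_reads = 0,
                                 max_pop_af = 0.01) {
  stopifnot(min_child_gq >= 0, min_depth >= 0, max_parent_alt_reads >= 0,
            max_pop_af >= 0)
  structure(as.list(environment()), class = "denovo_filter_config")
}

#' Detect de novo mutation candidates in trios
#'
#' A candidate is a site where both parents are homozygous reference
#' and the child is heterozygous (autosomal, biallelic) - a
#' Mendelian-inconsistent transmission pattern.  When the dataset
#' carries per-call quality matrices (`quality$GQ`, `quality$DP`,
#' `quality$parent_alt_reads`) the thresholds are applied; candidates
#' lacking quality fields are retained but flagged `unscored`.
#' Variants with a recorded population frequency above `max_pop_af`
#' are excluded.
#'
#' @param dataset a [trio_dataset()].
#' @param config a [denovo_filter_config()].
#' @return data frame: one row per candidate with `fid`, `variant`,
#'   `chrom`, `pos`, `ref`, `alt`, the transmission pattern and a
#'   `scored` flag.
#' @export
detect_candidates <- function(dataset, config = denovo_filter_config()) {
  fam <- dataset$families
  out <- list()
  qual <- dataset$quality
  for (i in seq_len(nrow(fam))) {
    if (is.na(fam$mother[i]) || is.na(fam$father[i]) || is.na(fam$child[i]))
      next
    m <- dataset$geno[, fam$mother[i]]
    f <- dataset$geno[, fam$father[i]]
    c <- dataset$geno[, fam$child[i]]
    hit <- which(!is.na(m) & !is.na(f) & !is.na(c) &
                   m == 0 & f == 0 & c == 1)
    for (v in hit) {
      va <- dataset$variants[v, ]
      if (isTRUE(va$is_indel)) next
      if (!is.null(va$pop_af) && !is.na(va$pop_af) &&
            va$pop_af > config$max_pop_af) next
      scored <- !is.null(qual)
      if (scored) {
        gq_ok <- qual$GQ[v, fam$child[i]] >= config$min_child_gq
        dp_ok <- all(qual$DP[v, c(fam$mother[i], fam$father[i],
                                  fam$child[i])] >= config$min_depth)
        ar_ok <- all(qual$parent_alt_reads[v, c(fam$mother[i],
                                                fam$father[i])] <=
                       config$max_parent_alt_reads)
        if (!(isTRUE(gq_ok) && isTRUE(dp_ok) && isTRUE(ar_ok))) next
      }
      out[[length(out) + 1]] <- data.frame(
        fid = fam$fid[i], variant = rownames(dataset$geno)[v],
        chrom = va$chrom, pos = va$pos, ref = va$ref, alt = va$alt,
        pattern = "0/0 x 0/0 -> 0/1", scored = scored,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(fid = character(0), variant = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      pattern = character(0), scored = logical(0)))
  do.call(rbind, out)
}

#' Per-trio regional mutation probability from per-base rates
#'
#' `p0 = 1 - prod(1 - mu_b)` over the per-base mutation rates of the
#' targeted region, evaluated in log space (`expm1`/`log1p`) so that
#' tiny rates do not vanish; approximately `sum(mu_b)` when all rates
#' are small.
#'
#' @param rates non-negative per-base mutation rates (all < 1).
#' @return scalar probability `p0`.
#' @export
region_mutation_prob <- function(rates) {
  stopifnot(all(rates >= 0))
  if (any(rates >= 1)) stop("per-base mutation rates must be < 1")
  if (!length(rates)) return(0)
  -expm1(sum(log1p(-rates)))
}

#' Exact upper binomial tail in log space
#'
#' `P(X >= k)` for `X ~ Bin(n, p)`, as the term-by-term sum
#' `sum_{j=k}^{n} C(n,j) p^j (1-p)^(n-j)` accumulated in log space
#' (log-sum-exp), so magnitudes down to ~1e-300 never underflow to 0
#' and retain full relative accuracy.
#'
#' @param n number of trials.
#' @param k observed count (tail starts here).
#' @param p success probability.
#' @return the tail probability.
#' @export
binomial_tail <- function(n, k, p) {
  stopifnot(n >= 0, k >= 0, k <= n, p >= 0, p <= 1)
  if (k == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  j <- k:n
  lt <- lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

#' De novo enrichment test
#'
#' Exact binomial test of whether the observed number of trios carrying
#' a de novo mutation exceeds expectation under the regional mutation
#' probability: `p_value = P(X >= k)`, `X ~ Bin(n_trios, p0)`.  (The
#' study convention treats trios as Bernoulli units, so `k` counts
#' mutation-carrying trios.)
#'
#' @param n_trios number of sequenced case trios.
#' @param k_observed observed de novo count.
#' @param p0 per-trio probability of at least one true de novo event in
#'   the targeted regions (see [region_mutation_prob()]).
#' @return list of class `denovo_enrichment`: `n`, `k`, `p0`,
#'   `expected`, `p_value`.
#' @export
denovo_enrichment <- function(n_trios, k_observed, p0) {
  stopifnot(p0 > 0, p0 < 1, k_observed >= 0, k_observed <= n_trios)
  structure(list(n = n_trios, k = k_observed, p0 = p0,
                 expected = n_trios * p0,
                 p_value = binomial_tail(n_trios, k_observed, p0)),
            class = "denovo_enrichment")
}

#' @export
print.denovo_enrichment <- function(x, ...) {
  cat(sprintf(paste0("de novo enrichment: %d of %d trios (expected %.3g",
                     " under p0 = %.6g)\n  exact binomial P(X >= %d) = %.3g\n"),
              x$k, x$n, x$expected, x$p0, x$k, x$p_value))
  invisible(x)
}
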