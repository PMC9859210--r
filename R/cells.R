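## Mendelian transmission machinery shared by the log-linear model, the
## simulator and QC.  Dosages count copies of the designated risk (minor)
## allele, so each parent transmits it with probability dose/2.

#' Mendelian transmission probability
#'
#' Probability that a child carries dosage `c` given parental dosages
#' `m` (mother) and `f` (father), under autosomal biallelic Mendelian
#' transmission: each parent independently transmits the counted allele
#' with probability dose/2.
#'
#' @param m,f,c integer dosages in 0:2 (vectorised).
#' @return numeric vector of probabilities.
#' @export
transmission_prob <- function(m, f, c) {
  pm <- m / 2
  pf <- f / 2
  # c = X + Y with X ~ Bern(pm), Y ~ Bern(pf)
  p <- numeric(length(c))
  p[c == 0] <- ((1 - pm) * (1 - pf))[c == 0]
  p[c == 1] <- (pm * (1 - pf) + (1 - pm) * pf)[c == 1]
  p[c == 2] <- (pm * pf)[c == 2]
  p
}

## unordered parental mating-type label: one of 6 classes
mating_type <- function(m, f) {
  lo <- pmin(m, f)
  hi <- pmax(m, f)
  paste0("mt", lo, hi)
}

#' The 15 Mendelian-compatible trio genotype cells
#'
#' All ordered (mother, father, child) dosage triples with positive
#' transmission probability, together with the transmission probability
#' and the unordered mating-type stratum (6 levels).  This table is the
#' index set of the trio log-linear likelihood.
#'
#' @return data frame with columns `m`, `f`, `c`, `trans` and `mt`.
#' @export
trio_cells <- function() {
  g <- expand.grid(c = 0:2, f = 0:2, m = 0:2)
  g <- g[, c("m", "f", "c")]
  g$trans <- transmission_prob(g$m, g$f, g$c)
  g <- g[g$trans > 0, , drop = FALSE]
  g$mt <- mating_type(g$m, g$f)
  rownames(g) <- NULL
  g
}

## key used to match observed trios against cells
cell_key <- function(m, f, c) paste(m, f, c, sep = "/")
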