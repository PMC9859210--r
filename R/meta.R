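## Two-phase combination: fixed-effect inverse-variance meta-analysis of
## log relative risks and Bayesian false-discovery probability (BFDP)
## noteworthiness ranking.

#' Build an effect estimate from a log relative risk and its SE
#'
#' @param log_rr log relative risk.
#' @param se standard error (> 0).
#' @param level confidence level (default 0.95).
#' @return list of class `effect_estimate` with `log_rr`, `se`, `rr`,
#'   `ci_low`, `ci_high`, `level`.
#' @export
effect_estimate <- function(log_rr, se, level = 0.95) {
  stopifnot(se > 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(log_rr = log_rr, se = se, rr = exp(log_rr),
                 ci_low = exp(log_rr - z * se),
                 ci_high = exp(log_rr + z * se), level = level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("RR %.3f [%.3f, %.3f] (log-RR %.4f, SE %.4f)\n",
              x$rr, x$ci_low, x$ci_high, x$log_rr, x$se))
  invisible(x)
}

#' Recover a log-scale SE from a printed RR confidence interval
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 z)`, the bridge that lets
#' published RR/CI columns feed the meta-analysis.
#'
#' @param rr point estimate (relative risk).
#' @param ci_low,ci_high interval bounds (0 < low < high).
#' @param level confidence level of the printed interval.
#' @return an [effect_estimate()] whose `log_rr` is `log(rr)`.
#' @export
se_from_ci <- function(rr, ci_low, ci_high, level = 0.95) {
  stopifnot(ci_low > 0, ci_high > ci_low)
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_estimate(log(rr), (log(ci_high) - log(ci_low)) / (2 * z), level)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines phase estimates with weights `1/SE^2` (via
#' `metafor::rma(method = "FE")`): the combined log-RR is the weighted
#' mean, its SE `1/sqrt(sum of weights)`, z and the two-sided normal p
#' follow.
#'
#' @param estimates list of [effect_estimate()] objects (>= 1).
#' @return list of class `meta_result`: `phases`, `weights`, `combined`
#'   (an effect estimate), `z`, `p`.
#' @export
fixed_effect_meta <- function(estimates) {
  if (inherits(estimates, "effect_estimate")) estimates <- list(estimates)
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "effect_estimate")))
  yi <- vapply(estimates, `[[`, 0, "log_rr")
  sei <- vapply(estimates, `[[`, 0, "se")
  if (any(sei <= 0)) stop("all standard errors must be positive")
  fit <- metafor::rma(yi = yi, sei = sei, method = "FE")
  comb <- effect_estimate(as.numeric(fit$beta), fit$se)
  structure(list(phases = estimates, weights = 1 / sei^2, combined = comb,
                 z = as.numeric(fit$zval), p = as.numeric(fit$pval)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat("fixed-effect meta-analysis of", length(x$phases), "phase(s)\n")
  for (i in seq_along(x$phases)) {
    cat(sprintf("  phase %d: ", i)); print(x$phases[[i]])
  }
  cat("  combined: "); print(x$combined)
  cat(sprintf("  z = %.3f, p = %.3g\n", x$z, x$p))
  invisible(x)
}

#' BFDP prior configuration
#'
#' The prior probability of association and the prior SD of the log
#' relative risk under the alternative.  The default prior SD,
#' `log(1.5)/qnorm(0.975)`, places 95% of the alternative's mass on
#' RR between 1/1.5 and 1.5.  Results are flagged noteworthy below the
#' conventional 0.8 threshold.
#'
#' @param prior_pi1 prior probability of a true association.
#' @param prior_sd prior SD (sqrt of W) on the log-RR scale.
#' @param noteworthy_threshold BFDP cut for noteworthiness.
#' @return list of class `bfdp_config`.
#' @export
bfdp_config <- function(prior_pi1 = 0.05,
                        prior_sd = log(1.5) / stats::qnorm(0.975),
                        noteworthy_threshold = 0.8) {
  stopifnot(prior_pi1 > 0, prior_pi1 < 1, prior_sd > 0)
  structure(list(prior_pi1 = prior_pi1, prior_sd = prior_sd,
                 noteworthy_threshold = noteworthy_threshold),
            class = "bfdp_config")
}

#' Bayesian false-discovery probability
#'
#' With estimate variance `V = se^2` and prior variance `W`, the
#' approximate Bayes factor in favour of the null is
#' `ABF01 = sqrt((V + W)/V) * exp(-z^2 W / (2 (V + W)))` with
#' `z = log_rr / se`, and
#' `BFDP = ABF01 * PO0 / (ABF01 * PO0 + 1)` where
#' `PO0 = (1 - pi1)/pi1` is the prior odds of no association.
#'
#' @param estimate an [effect_estimate()].
#' @param config a [bfdp_config()].
#' @return the BFDP, a probability; the prior used is attached as
#'   attribute `"prior"`.
#' @export
bfdp <- function(estimate, config = bfdp_config()) {
  stopifnot(inherits(estimate, "effect_estimate"))
  V <- estimate$se^2
  W <- config$prior_sd^2
  z <- estimate$log_rr / estimate$se
  abf01 <- sqrt((V + W) / V) * exp(-z^2 * W / (2 * (V + W)))
  po0 <- (1 - config$prior_pi1) / config$prior_pi1
  out <- abf01 * po0 / (abf01 * po0 + 1)
  attr(out, "prior") <- c(pi1 = config$prior_pi1, sd = config$prior_sd)
  out
}

#' Filter a result table to noteworthy associations
#'
#' Keeps rows with `p_meta < p_threshold` AND
#' `bfdp_meta < noteworthy_threshold` (both conditions required),
#' sorted by `p_meta` ascending.
#'
#' @param table data frame with columns `p_meta` and `bfdp_meta`.
#' @param config a [bfdp_config()] (supplies the BFDP threshold).
#' @param p_threshold meta-analysis p-value cut (default 0.05).
#' @return the filtered, sorted data frame.
#' @export
rank_noteworthy <- function(table, config = bfdp_config(),
                            p_threshold = 0.05) {
  stopifnot(all(c("p_meta", "bfdp_meta") %in% names(table)))
  keep <- !is.na(table$p_meta) & !is.na(table$bfdp_meta) &
    table$p_meta < p_threshold &
    table$bfdp_meta < config$noteworthy_threshold
  out <- table[keep, , drop = FALSE]
  out[order(out$p_meta), , drop = FALSE]
}
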