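## Exposure-stratified log-linear model for case-parent trios.
##
## Complete case trios are cross-classified over the 15 Mendelian-
## compatible (mother, father, child) dosage cells.  The cell mean is
##
##   mu_mfc = exp(gamma_S(m,f)) * T(c | m, f) * exp(b_f c + b_m m)
##
## with S(m,f) the unordered parental mating type (6 nuisance levels),
## T Mendelian transmission, b_f / b_m the log per-allele fetal and
## maternal relative risks (log-additive coding; codominant replaces
## the linear terms with dosage indicators).  Maximisation is by
## Poisson regression; families with missing members enter through an
## EM algorithm that distributes each incomplete family over its
## compatible complete cells in proportion to the current cell means.
## Control trios are excluded by default (the trio likelihood does not
## need them); optionally they inform the mating-type parameters only.

#' Tabulate a variant into trio genotype cell counts
#'
#' Complete case trios increment their (m, f, c, stratum) cell;
#' incomplete case families (at least one member observed) are stored
#' verbatim for the EM; control families are kept in a separate block
#' that the fitter may use to inform mating-type frequencies only.
#' Mendelian-inconsistent trios are excluded with a warning (QC should
#' have masked them).
#'
#' @param dataset a [trio_dataset()] with an exposure table.
#' @param variant variant id (row name of the genotype matrix).
#' @return object of class `trio_cell_counts`: `cells` (the 15-cell
#'   table with one count column per stratum), `incomplete` (data frame
#'   m/f/c/stratum with `NA` for missing members), `control` (complete
#'   control-trio cell counts), `variant`.
#' @export
tabulate_trios <- function(dataset, variant) {
  cells <- trio_cells()
  key <- cell_key(cells$m, cells$f, cells$c)
  d <- family_dosages(dataset, variant)
  d$stratum <- family_exposure(dataset)
  counts <- matrix(0, nrow(cells), 2,
                   dimnames = list(key, c("unexposed", "exposed")))
  ctrl <- matrix(0, nrow(cells), 2,
                 dimnames = list(key, c("unexposed", "exposed")))
  inc <- list()
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    complete <- !is.na(r$m) && !is.na(r$f) && !is.na(r$c)
    if (!isTRUE(r$affected)) {
      if (complete) {
        k <- cell_key(r$m, r$f, r$c)
        if (k %in% key) ctrl[k, r$stratum] <- ctrl[k, r$stratum] + 1
      }
      next
    }
    if (complete) {
      if (mendelian_check(r$m, r$f, r$c) == "inconsistent") {
        warning("family ", r$fid, " Mendelian-inconsistent at ", variant,
                "; excluded")
        next
      }
      counts[cell_key(r$m, r$f, r$c), r$stratum] <-
        counts[cell_key(r$m, r$f, r$c), r$stratum] + 1
    } else if (!all(is.na(c(r$m, r$f, r$c)))) {
      inc[[length(inc) + 1]] <- data.frame(m = r$m, f = r$f, c = r$c,
                                           stratum = r$stratum)
    }
  }
  incomplete <- if (length(inc)) do.call(rbind, inc) else
    data.frame(m = integer(0), f = integer(0), c = integer(0),
               stratum = character(0))
  structure(list(cells = cells, counts = counts, control = ctrl,
                 incomplete = incomplete, variant = variant),
            class = "trio_cell_counts")
}

#' @export
print.trio_cell_counts <- function(x, ...) {
  cat("trio cell counts for", x$variant, "\n")
  cat("  complete case trios:", sum(x$counts), " (",
      paste(colnames(x$counts), colSums(x$counts), collapse = ", "), ")\n")
  cat("  incomplete case families:", nrow(x$incomplete), "\n")
  cat("  control trios:", sum(x$control), "\n")
  invisible(x)
}

## genetic design matrix over cells
genetic_design <- function(cells, coding, include_maternal) {
  if (coding == "log-additive") {
    X <- cbind(beta_fetal = cells$c)
    if (include_maternal) X <- cbind(X, beta_maternal = cells$m)
  } else if (coding == "codominant") {
    X <- cbind(beta_fetal1 = as.numeric(cells$c == 1),
               beta_fetal2 = as.numeric(cells$c == 2))
    if (include_maternal)
      X <- cbind(X, beta_maternal1 = as.numeric(cells$m == 1),
                 beta_maternal2 = as.numeric(cells$m == 2))
  } else stop("unknown coding: ", coding)
  X
}

## compatible retained-cell indices for one incomplete record
compatible_cells <- function(cells, m, f, c) {
  ok <- rep(TRUE, nrow(cells))
  if (!is.na(m)) ok <- ok & cells$m == m
  if (!is.na(f)) ok <- ok & cells$f == f
  if (!is.na(c)) ok <- ok & cells$c == c
  which(ok)
}

## observed-data multinomial log-likelihood over one stratum's design.
## theta = (beta, gamma[-1]); gamma reference level fixed at 0 (the
## multinomial scale is not identified).  `blocks`: list(n = complete
## counts, X, g_idx, log_trans, delta_idx); incomplete = list of cell
## index vectors (one per family).
obs_loglik_factory <- function(n, X, g_idx, log_trans, incomplete,
                               n_gamma, extra = NULL) {
  p <- ncol(X)
  function(theta) {
    beta <- theta[seq_len(p)]
    gam <- c(0, theta[p + seq_len(n_gamma - 1)])
    logmu <- gam[g_idx] + log_trans + drop(X %*% beta)
    if (!is.null(extra)) logmu <- logmu + extra(theta)
    mu <- exp(logmu)
    tot <- sum(mu)
    ll <- sum(n[n > 0] * logmu[n > 0])
    for (A in incomplete) ll <- ll + log(sum(mu[A]))
    ll - (sum(n) + length(incomplete)) * log(tot)
  }
}

## numerical central-difference Hessian (step 1e-5)
num_hessian <- function(fn, theta, h = 1e-5) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in i:p) {
    e_i <- e_j <- rep(0, p); e_i[i] <- h; e_j[j] <- h
    H[i, j] <- H[j, i] <-
      (fn(theta + e_i + e_j) - fn(theta + e_i - e_j) -
         fn(theta - e_i + e_j) + fn(theta - e_i - e_j)) / (4 * h^2)
  }
  H
}

## Poisson M-step on (possibly fractional) completed counts
mstep_glm <- function(count, X, g_idx, log_trans, ctrl_ind = NULL) {
  df <- data.frame(count = count, g = factor(g_idx))
  form <- count ~ 0 + g
  if (!is.null(ctrl_ind)) { df$ctrl <- ctrl_ind; form <- count ~ 0 + g + ctrl }
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- X[, j]
  form <- stats::update(form, paste("~ . +",
                                    paste(colnames(X), collapse = "+")))
  fit <- suppressWarnings(stats::glm(form, family = stats::poisson(),
                                     offset = log_trans, data = df,
                                     control = stats::glm.control(
                                       epsilon = 1e-12, maxit = 100)))
  fit
}

#' Fit the trio log-linear model for one exposure stratum
#'
#' Maximises the Weinberg-Umbach Poisson log-linear likelihood over the
#' Mendelian-compatible trio cells; incomplete families are handled by
#' EM (E-step distributes each family over its compatible cells in
#' proportion to the current cell means, M-step refits the Poisson
#' regression).  Standard errors come from the numerically
#' differentiated observed-data log-likelihood; with no incomplete
#' family the fit equals the complete-data Poisson fit.
#'
#' @param counts a [tabulate_trios()] object.
#' @param stratum `"unexposed"` or `"exposed"`.
#' @param include_maternal estimate the maternal effect (default `TRUE`).
#' @param coding `"log-additive"` (per-allele, default) or
#'   `"codominant"` (dosage indicators).
#' @param em_tol convergence tolerance on the observed log-likelihood.
#' @param max_iter EM iteration cap.
#' @param use_controls let complete control trios inform the
#'   mating-type parameters (hybrid design); they never contribute to
#'   the genetic effects.
#' @param use_incomplete include incomplete families through EM
#'   (default) or drop them.
#' @param compute_se evaluate the numerically differentiated
#'   observed-data information (default `TRUE`); skip it (`FALSE`) when
#'   only point estimates and log-likelihoods are needed, e.g. in
#'   LRT-only simulation loops.
#' @return object of class `trio_loglin` with elements `coef`, `se`,
#'   `vcov`, `gamma`, `loglik` (observed-data), `n_complete`,
#'   `n_incomplete`, `converged`, `flags`, `em_trace`, `cells`.
#' @export
trio_loglin <- function(counts, stratum = "unexposed",
                        include_maternal = TRUE, coding = "log-additive",
                        em_tol = 1e-8, max_iter = 500,
                        use_controls = FALSE, use_incomplete = TRUE,
                        compute_se = TRUE) {
  stopifnot(inherits(counts, "trio_cell_counts"),
            stratum %in% c("unexposed", "exposed"), em_tol > 0)
  cells <- counts$cells
  n <- counts$counts[, stratum]
  inc <- counts$incomplete
  inc <- inc[inc$stratum == stratum, , drop = FALSE]
  if (!use_incomplete) inc <- inc[0, , drop = FALSE]

  inc_cells <- lapply(seq_len(nrow(inc)), function(i)
    compatible_cells(cells, inc$m[i], inc$f[i], inc$c[i]))
  inc_cells <- inc_cells[lengths(inc_cells) > 0]

  ## retain mating types with any possible mass
  mt_alive <- tapply(n, cells$mt, sum) > 0
  for (A in inc_cells) mt_alive[unique(cells$mt[A])] <- TRUE
  nc <- counts$control[, stratum] + counts$control[, setdiff(c("unexposed", "exposed"), stratum)]
  if (use_controls) mt_alive[unique(cells$mt[nc > 0])] <- TRUE
  keep <- cells$mt %in% names(mt_alive)[mt_alive]
  cells <- cells[keep, , drop = FALSE]
  n <- n[keep]
  remap <- function(A) match(A, which(keep))
  inc_cells <- lapply(inc_cells, function(A) remap(A)[!is.na(remap(A))])

  if (sum(n) + length(inc_cells) == 0)
    stop("no case families informative for ", counts$variant,
         " in stratum ", stratum)

  X <- genetic_design(cells, coding, include_maternal)
  g_fac <- factor(cells$mt)
  g_idx <- as.integer(g_fac)
  n_gamma <- nlevels(g_fac)
  log_trans <- log(cells$trans)

  ## optional control block: same gamma, own intercept, no beta
  if (use_controls && sum(nc[keep]) > 0) {
    nb <- c(n, nc[keep])
    Xb <- rbind(X, matrix(0, nrow(cells), ncol(X),
                          dimnames = list(NULL, colnames(X))))
    gb <- c(g_idx, g_idx)
    ltb <- c(log_trans, log_trans)
    ctrl_ind <- c(rep(0, nrow(cells)), rep(1, nrow(cells)))
  } else {
    nb <- n; Xb <- X; gb <- g_idx; ltb <- log_trans; ctrl_ind <- NULL
    use_controls <- FALSE
  }
  ncase_cells <- nrow(cells)

  loglik_fn <- local({
    nn <- n; XX <- X; gi <- g_idx; lt <- log_trans
    obs_loglik_factory(nn, XX, gi, lt, inc_cells, n_gamma)
  })

  em_trace <- numeric(0)
  frac <- rep(0, nrow(cells))      # EM fractional counts from incomplete
  fit <- NULL
  converged <- TRUE
  if (length(inc_cells) == 0) {
    fit <- mstep_glm(nb, Xb, gb, ltb, ctrl_ind)
    iter <- 0L
  } else {
    ## init: distribute incomplete families uniformly
    for (A in inc_cells) frac[A] <- frac[A] + 1 / length(A)
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      fit <- mstep_glm(c(n + frac, nb[-seq_len(length(n))]),
                       Xb, gb, ltb, ctrl_ind)
      mu <- fit$fitted.values[seq_len(ncase_cells)]
      theta_now <- extract_theta(fit, colnames(X), n_gamma)
      ll <- loglik_fn(theta_now)
      em_trace <- c(em_trace, ll)
      if (ll < ll_old - 1e-8)
        warning("EM log-likelihood decreased at iteration ", iter)
      if (is.finite(ll_old) && abs(ll - ll_old) < em_tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      frac <- rep(0, ncase_cells)
      for (A in inc_cells) frac[A] <- frac[A] + mu[A] / sum(mu[A])
    }
  }

  theta <- extract_theta(fit, colnames(X), n_gamma)
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)

  flags <- character(0)
  if (!fit$converged) { converged <- FALSE; flags <- c(flags, "glm") }
  if (any(abs(beta) > 10))
    flags <- c(flags, paste0("separation:",
                             paste(names(beta)[abs(beta) > 10],
                                   ifelse(beta[abs(beta) > 10] > 0, "+", "-"),
                                   collapse = ",")))

  ## observed-data information (case block only; controls add no
  ## information on beta beyond gamma, included via their own loglik)
  vc <- matrix(NA_real_, p, p, dimnames = list(names(beta), names(beta)))
  se <- rep(NA_real_, p)
  if (compute_se && !length(flags)) {
    H <- num_hessian(if (use_controls) joint_control_loglik(
      n, X, g_idx, log_trans, inc_cells, n_gamma, nc[keep]) else loglik_fn,
      theta)
    V <- try(solve(-H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V)[seq_len(p)] > 0)) {
      vc <- V[seq_len(p), seq_len(p), drop = FALSE]
      dimnames(vc) <- list(names(beta), names(beta))
      se <- sqrt(diag(vc))
    } else flags <- c(flags, "information")
  }
  names(se) <- names(beta)

  gam <- c(0, theta[p + seq_len(n_gamma - 1)])
  names(gam) <- levels(g_fac)
  ll_final <- loglik_fn(theta)

  out <- list(coef = beta, se = se, vcov = vc, gamma = gam,
              loglik = ll_final, n_complete = sum(n),
              n_incomplete = length(inc_cells),
              converged = converged && !length(flags), flags = flags,
              em_trace = em_trace, stratum = stratum,
              coding = coding, include_maternal = include_maternal,
              cells = cbind(cells, count = n,
                            fitted = fit$fitted.values[seq_len(ncase_cells)]),
              variant = counts$variant, glm_fit = fit)
  class(out) <- "trio_loglin"
  out
}

## theta = (beta, gamma[-1] relative to first level), mapped from glm coefs
extract_theta <- function(fit, beta_names, n_gamma) {
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  gam <- cf[paste0("g", seq_len(n_gamma))]
  gam[is.na(gam)] <- min(gam, na.rm = TRUE) - 20   # empty level
  beta <- cf[beta_names]
  beta[is.na(beta)] <- 0
  unname(c(beta, gam[-1] - gam[1]))
}

## observed loglik when controls inform gamma: case multinomial plus an
## independent control multinomial sharing gamma (beta absent)
joint_control_loglik <- function(n, X, g_idx, log_trans, inc_cells,
                                 n_gamma, nctrl) {
  case_ll <- obs_loglik_factory(n, X, g_idx, log_trans, inc_cells, n_gamma)
  p <- ncol(X)
  function(theta) {
    gam <- c(0, theta[p + seq_len(n_gamma - 1)])
    logmu <- gam[g_idx] + log_trans
    mu <- exp(logmu)
    ll_ctrl <- sum(nctrl[nctrl > 0] * logmu[nctrl > 0]) -
      sum(nctrl) * log(sum(mu))
    case_ll(theta) + ll_ctrl
  }
}

#' @export
print.trio_loglin <- function(x, ...) {
  cat("trio log-linear fit (", x$stratum, " stratum, ", x$coding,
      " coding)\n", sep = "")
  cat("  complete trios:", x$n_complete,
      " incomplete families:", x$n_incomplete, "\n")
  est <- exp(x$coef)
  for (i in seq_along(est))
    cat(sprintf("  %-15s RR = %.3f (log-RR %.4f, SE %.4f)\n",
                names(est)[i], est[i], x$coef[i], x$se[i]))
  if (!x$converged) cat("  ** flagged:", paste(x$flags, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.trio_loglin <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tab <- data.frame(
    estimate = object$coef, se = object$se, rr = exp(object$coef),
    ci_low = exp(object$coef - z * object$se),
    ci_high = exp(object$coef + z * object$se),
    z = object$coef / object$se,
    p = 2 * stats::pnorm(-abs(object$coef / object$se)))
  structure(list(table = tab, fit = object, level = level),
            class = "summary.trio_loglin")
}

#' @export
print.summary.trio_loglin <- function(x, ...) {
  print(x$fit)
  cat("\nRelative risks (", 100 * x$level, "% CI):\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
coef.trio_loglin <- function(object, ...) object$coef

#' @export
vcov.trio_loglin <- function(object, ...) object$vcov

#' @export
logLik.trio_loglin <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coef) + length(object$gamma) - 1,
            class = "logLik")
}

#' @export
confint.trio_loglin <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coef - z * object$se, object$coef + z * object$se)
  colnames(ci) <- paste(100 * c((1 - level) / 2, 1 - (1 - level) / 2), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.trio_loglin <- function(object, ...) {
  stats::setNames(object$cells$fitted,
                  cell_key(object$cells$m, object$cells$f, object$cells$c))
}

#' @export
residuals.trio_loglin <- function(object, type = "pearson", ...) {
  obs <- object$cells$count
  mu <- object$cells$fitted
  r <- switch(type,
              pearson = (obs - mu) / sqrt(pmax(mu, .Machine$double.eps)),
              response = obs - mu,
              stop("unknown residual type"))
  stats::setNames(r, cell_key(object$cells$m, object$cells$f, object$cells$c))
}

#' @export
simulate.trio_loglin <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- object$cells$fitted / sum(object$cells$fitted)
  n <- object$n_complete
  out <- as.data.frame(stats::rmultinom(nsim, n, pr))
  rownames(out) <- cell_key(object$cells$m, object$cells$f, object$cells$c)
  out
}

## joint two-stratum fit; share_beta = TRUE gives the null for the LRT
fit_joint <- function(counts, include_maternal, coding, em_tol, max_iter,
                      share_beta) {
  cells1 <- counts$cells
  strata <- c("unexposed", "exposed")
  big <- do.call(rbind, lapply(strata, function(s) {
    cc <- cells1
    cc$stratum <- s
    cc$count <- counts$counts[, s]
    cc
  }))
  inc <- counts$incomplete
  inc_cells <- list()
  for (i in seq_len(nrow(inc))) {
    off <- if (inc$stratum[i] == "unexposed") 0 else nrow(cells1)
    A <- compatible_cells(cells1, inc$m[i], inc$f[i], inc$c[i])
    if (length(A)) inc_cells[[length(inc_cells) + 1]] <- A + off
  }
  mtst <- paste(big$mt, big$stratum)
  alive <- tapply(big$count, mtst, sum) > 0
  for (A in inc_cells) alive[unique(mtst[A])] <- TRUE
  keep <- mtst %in% names(alive)[alive]
  remap <- cumsum(keep)
  inc_cells <- lapply(inc_cells, function(A) remap[A][keep[A]])
  inc_cells <- inc_cells[lengths(inc_cells) > 0]
  big <- big[keep, , drop = FALSE]

  X0 <- genetic_design(big, coding, include_maternal)
  if (!share_beta) {
    e <- as.numeric(big$stratum == "exposed")
    Xe <- X0 * e
    colnames(Xe) <- paste0(colnames(X0), "_x_exposed")
    X <- cbind(X0, Xe)
  } else X <- X0
  g_fac <- factor(paste(big$mt, big$stratum))
  g_idx <- as.integer(g_fac)
  n_gamma <- nlevels(g_fac)
  log_trans <- log(big$trans)
  n <- big$count
  loglik_fn <- obs_loglik_factory(n, X, g_idx, log_trans, inc_cells, n_gamma)

  if (!length(inc_cells)) {
    fit <- mstep_glm(n, X, g_idx, log_trans)
    theta <- extract_theta(fit, colnames(X), n_gamma)
    return(list(loglik = loglik_fn(theta), npar = ncol(X),
                theta = theta, converged = fit$converged))
  }
  frac <- rep(0, nrow(big))
  for (A in inc_cells) frac[A] <- frac[A] + 1 / length(A)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fit <- mstep_glm(n + frac, X, g_idx, log_trans)
    mu <- fit$fitted.values
    theta <- extract_theta(fit, colnames(X), n_gamma)
    ll <- loglik_fn(theta)
    if (is.finite(ll_old) && abs(ll - ll_old) < em_tol) { converged <- TRUE; break }
    ll_old <- ll
    frac <- rep(0, nrow(big))
    for (A in inc_cells) frac[A] <- frac[A] + mu[A] / sum(mu[A])
  }
  list(loglik = ll, npar = ncol(X), theta = theta,
       converged = converged && fit$converged)
}

#' Gene-environment interaction test between exposure strata
#'
#' Wald contrast of the stratum-specific genetic log relative risks,
#' `z = (b_unexposed - b_exposed) / sqrt(SE0^2 + SE1^2)` per genetic
#' parameter, plus a likelihood-ratio test comparing the joint model
#' with stratum-specific genetic effects against shared effects
#' (df = number of genetic parameters).
#'
#' @param fit_unexposed,fit_exposed per-stratum [trio_loglin()] fits of
#'   the same variant and specification.
#' @param counts the [tabulate_trios()] object (for the joint refit).
#' @return object of class `trio_gxe`: per-parameter table (`estimates`)
#'   with Wald z and p, overall `p_lrt`, and a `reliable` flag.
#' @export
gxe_test <- function(fit_unexposed, fit_exposed, counts) {
  stopifnot(fit_unexposed$coding == fit_exposed$coding,
            fit_unexposed$include_maternal == fit_exposed$include_maternal)
  b0 <- fit_unexposed$coef; s0 <- fit_unexposed$se
  b1 <- fit_exposed$coef;   s1 <- fit_exposed$se
  delta <- b0 - b1
  se_d <- sqrt(s0^2 + s1^2)
  z <- delta / se_d
  est <- data.frame(
    parameter = names(b0),
    beta_unexposed = b0, se_unexposed = s0,
    beta_exposed = b1, se_exposed = s1,
    delta = delta, se_delta = se_d, z = z,
    p_wald = 2 * stats::pnorm(-abs(z)), row.names = NULL)

  reliable <- fit_unexposed$converged && fit_exposed$converged
  p_lrt <- NA_real_
  if (reliable) {
    null_fit <- fit_joint(counts, fit_unexposed$include_maternal,
                          fit_unexposed$coding, 1e-8, 500, share_beta = TRUE)
    alt_fit <- fit_joint(counts, fit_unexposed$include_maternal,
                         fit_unexposed$coding, 1e-8, 500, share_beta = FALSE)
    df <- alt_fit$npar - null_fit$npar
    lr <- 2 * (alt_fit$loglik - null_fit$loglik)
    p_lrt <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
  }
  structure(list(estimates = est, p_lrt = p_lrt, reliable = reliable,
                 variant = counts$variant), class = "trio_gxe")
}

#' @export
print.trio_gxe <- function(x, ...) {
  cat("gene-environment interaction test,", x$variant, "\n")
  print(x$estimates[, c("parameter", "delta", "z", "p_wald")])
  cat("LRT p =", format(x$p_lrt, digits = 4),
      if (!x$reliable) " (UNRELIABLE: a stratum fit is flagged)" else "",
      "\n")
  invisible(x)
}

#' Per-variant gene-environment interaction scan
#'
#' Fits both exposure strata and the interaction test for every
#' requested variant.  Untestable variants (no informative families, or
#' flagged fits) yield flagged rows rather than being dropped.
#'
#' @param dataset a [trio_dataset()] with exposure table.
#' @param variants variant ids (default: all).
#' @param include_maternal,coding,em_tol,max_iter,use_controls,use_incomplete
#'   passed to [trio_loglin()].
#' @return data frame, one row per variant: per-stratum relative risks
#'   with 95% CIs for each genetic parameter, Wald and LRT interaction
#'   p-values, and a `flag` column.
#' @export
scan_gxe <- function(dataset, variants = NULL, include_maternal = TRUE,
                     coding = "log-additive", em_tol = 1e-8, max_iter = 500,
                     use_controls = FALSE, use_incomplete = TRUE) {
  if (is.null(variants)) variants <- rownames(dataset$geno)
  rows <- lapply(variants, function(v) {
    res <- try(suppressWarnings({
      cc <- tabulate_trios(dataset, v)
      f0 <- trio_loglin(cc, "unexposed", include_maternal, coding,
                        em_tol, max_iter, use_controls, use_incomplete)
      f1 <- trio_loglin(cc, "exposed", include_maternal, coding,
                        em_tol, max_iter, use_controls, use_incomplete)
      gx <- gxe_test(f0, f1, cc)
      list(f0 = f0, f1 = f1, gx = gx)
    }), silent = TRUE)
    base <- data.frame(variant = v, stringsAsFactors = FALSE)
    if (inherits(res, "try-error")) {
      base$flag <- "untestable"
      return(base)
    }
    z <- stats::qnorm(0.975)
    for (i in seq_along(res$f0$coef)) {
      nm <- sub("^beta_", "", names(res$f0$coef)[i])
      base[[paste0("rr_", nm, "_unexposed")]] <- exp(res$f0$coef[i])
      base[[paste0("rr_", nm, "_unexposed_lo")]] <-
        exp(res$f0$coef[i] - z * res$f0$se[i])
      base[[paste0("rr_", nm, "_unexposed_hi")]] <-
        exp(res$f0$coef[i] + z * res$f0$se[i])
      base[[paste0("rr_", nm, "_exposed")]] <- exp(res$f1$coef[i])
      base[[paste0("rr_", nm, "_exposed_lo")]] <-
        exp(res$f1$coef[i] - z * res$f1$se[i])
      base[[paste0("rr_", nm, "_exposed_hi")]] <-
        exp(res$f1$coef[i] + z * res$f1$se[i])
      base[[paste0("p_wald_", nm)]] <- res$gx$estimates$p_wald[i]
      base[[paste0("delta_", nm)]] <- res$gx$estimates$delta[i]
      base[[paste0("se_delta_", nm)]] <- res$gx$estimates$se_delta[i]
    }
    base$p_lrt <- res$gx$p_lrt
    base$flag <- if (res$gx$reliable) "" else
      paste(unique(c(res$f0$flags, res$f1$flags, "unreliable")),
            collapse = ";")
    base
  })
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_names, names(r))) r[[nm]] <- NA
    r[all_names]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
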