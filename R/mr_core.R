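#' @title Two-sample MR estimators, diagnostics and reporting arithmetic
#' @description Per-variant Wald ratios with first-order delta standard
#'   errors are combined by inverse-variance weighting (with multiplicative
#'   random-effects inflation), MR-Egger regression, the weighted median and
#'   the weighted mode. Cochran's Q quantifies heterogeneity, the Egger
#'   intercept directional pleiotropy, and leave-one-out analysis flags
#'   influential instruments. For binary outcomes results are rendered as
#'   odds ratios per 1-SD change in the exposure with 95% confidence
#'   intervals, and families of results are corrected by Benjamini-Hochberg
#'   false discovery rate.
#' @name mr-core
NULL

mr_result <- function(method, n_snp, beta, se, pval, level = 0.95,
                      q_stat = NA_real_, q_pval = NA_real_,
                      egger_intercept = NA_real_,
                      egger_intercept_pval = NA_real_) {
  ci <- or_ci(beta, se, level)
  data.frame(method = method, n_snp = as.integer(n_snp), beta = beta,
             se = se, pval = pval, or = ci$or, ci_low = ci$ci_low,
             ci_high = ci$ci_high, q_stat = q_stat, q_pval = q_pval,
             egger_intercept = egger_intercept,
             egger_intercept_pval = egger_intercept_pval,
             pfdr = NA_real_)
}

# Per-SNP Wald ratios with first-order delta standard errors; SNPs with a
# zero exposure effect carry no ratio information and are dropped with a
# warning.
ratio_estimates <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  zero <- pair$beta_x == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " SNP(s) with zero exposure effect: ",
            paste(pair$snp_id[zero], collapse = ", "), call. = FALSE)
    pair <- pair_subset(pair, !zero)
  }
  data.frame(snp_id = pair$snp_id, ratio = pair$beta_y / pair$beta_x,
             se_ratio = pair$se_y / abs(pair$beta_x))
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_y/beta_x`, `se = se_y/|beta_x|` (first-order delta method),
#' two-sided normal p-value.
#'
#' @param pair a `harmonized_pair` with exactly one SNP.
#' @param level confidence level for the odds-ratio interval.
#' @return One-row MR result data frame.
#' @export
wald_ratio <- function(pair, level = 0.95) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (nrow(pair) != 1L) {
    stop("wald_ratio() requires exactly one SNP", call. = FALSE)
  }
  if (pair$beta_x == 0) {
    stop("wald_ratio(): exposure effect is zero, ratio undefined",
         call. = FALSE)
  }
  beta <- pair$beta_y / pair$beta_x
  se <- pair$se_y / abs(pair$beta_x)
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("wald", 1L, beta, se, pval, level)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted mean of the per-SNP ratios with weights `1/se_ratio^2`. The
#' fixed-effect standard error is inflated by
#' `sqrt(max(1, Q/(k-1)))` (multiplicative random effects: over-dispersion
#' is absorbed, never deflated). Cochran's Q and its p-value are attached.
#' SNPs with a zero exposure effect are dropped with a warning; with fewer
#' than two survivors the estimate falls back to the Wald ratio.
#'
#' @param pair a `harmonized_pair` with at least 2 SNPs.
#' @param level confidence level.
#' @return One-row MR result data frame.
#' @export
ivw <- function(pair, level = 0.95) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (nrow(pair) < 1L) stop("ivw(): empty pair", call. = FALSE)
  re <- ratio_estimates(pair)
  k <- nrow(re)
  if (k < 2L) {
    return(wald_ratio(pair_subset(pair, pair$snp_id %in% re$snp_id), level))
  }
  w <- 1 / re$se_ratio^2
  beta <- sum(w * re$ratio) / sum(w)
  q <- cochran_q(re$ratio, re$se_ratio, beta)
  se <- sqrt(1 / sum(w)) * sqrt(max(1, q$q_stat / (k - 1)))
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_result("ivw", k, beta, se, pval, level,
            q_stat = q$q_stat, q_pval = q$q_pval)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `1/se_y^2`, after orienting every exposure effect
#' non-negative (flipping the outcome effect accordingly). The slope is the
#' causal estimate; a non-zero intercept indicates directional pleiotropy.
#' Standard errors use multiplicative over-dispersion floored at 1;
#' p-values are two-sided t with `k-2` degrees of freedom.
#'
#' @param pair a `harmonized_pair` with at least 3 SNPs.
#' @param level confidence level.
#' @return One-row MR result data frame (with `egger_intercept` fields), or
#'   `NULL` with a warning when fewer than 3 SNPs are available.
#' @export
mr_egger <- function(pair, level = 0.95) {
  stopifnot(inherits(pair, "harmonized_pair"))
  k <- nrow(pair)
  if (k < 3L) {
    warning("mr_egger() requires >= 3 SNPs; not applicable", call. = FALSE)
    return(NULL)
  }
  flip <- pair$beta_x < 0
  bx <- abs(pair$beta_x)
  by <- ifelse(flip, -pair$beta_y, pair$beta_y)
  w <- 1 / pair$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  disp <- min(1, sm$sigma)  # enforce multiplicative dispersion >= 1
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"] / disp
  pvals <- 2 * stats::pt(-abs(est / se), df = k - 2)
  # Rucker's Q for the Egger model
  q_stat <- sum(w * stats::residuals(fit)^2)
  q_pval <- stats::pchisq(q_stat, df = k - 2, lower.tail = FALSE)
  mr_result("egger", k, est[["bx"]], se[["bx"]], pvals[["bx"]], level,
            q_stat = q_stat, q_pval = q_pval,
            egger_intercept = est[["(Intercept)"]],
            egger_intercept_pval = pvals[["(Intercept)"]])
}

#' Weighted median estimate
#'
#' The value at cumulative normalized inverse-variance weight one half of
#' the ordered ratio estimates, with linear interpolation; consistent when
#' at least half the weight comes from valid instruments. The standard
#' error is a seeded parametric bootstrap.
#'
#' @param pair a `harmonized_pair` with at least 3 SNPs.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed bootstrap seed (recorded in the result attributes).
#' @param level confidence level.
#' @return One-row MR result data frame.
#' @export
weighted_median <- function(pair, n_boot = 1000, seed = 1L, level = 0.95) {
  stopifnot(inherits(pair, "harmonized_pair"))
  if (nrow(pair) < 3L) {
    stop("weighted_median() requires >= 3 SNPs", call. = FALSE)
  }
  re <- ratio_estimates(pair)
  est <- weighted_percentile(re$ratio, 1 / re$se_ratio^2, 0.5)
  se <- boot_se(pair, seed, n_boot, function(b, w) {
    weighted_percentile(b, w, 0.5)
  })
  pval <- 2 * stats::pnorm(-abs(est / se))
  out <- mr_result("weighted_median", nrow(re), est, se, pval, level)
  attr(out, "boot_seed") <- seed
  out
}

#' Weighted mode estimate
#'
#' The mode of the inverse-variance-weighted normal-kernel density of the
#' ratio estimates, with bandwidth `bandwidth_factor` times a weighted
#' MAD-based scale (falling back to the weighted standard deviation when the
#' MAD degenerates); consistent when the largest group of instruments
#' sharing a ratio is valid. Standard error by seeded parametric bootstrap.
#' When all ratios coincide the common ratio is returned with zero standard
#' error.
#'
#' @param pair a `harmonized_pair` with at least 3 SNPs.
#' @param bandwidth_factor kernel bandwidth multiplier (default 1).
#' @param n_boot,seed,level as for [weighted_median()].
#' @return One-row MR result data frame.
#' @export
weighted_mode <- function(pair, bandwidth_factor = 1, n_boot = 1000,
                          seed = 1L, level = 0.95) {
  stopifnot(inherits(pair, "harmonized_pair"), bandwidth_factor > 0)
  if (nrow(pair) < 3L) {
    stop("weighted_mode() requires >= 3 SNPs", call. = FALSE)
  }
  re <- ratio_estimates(pair)
  w <- 1 / re$se_ratio^2
  if (max(re$ratio) - min(re$ratio) < 1e-12) {
    out <- mr_result("weighted_mode", nrow(re), re$ratio[1L], 0, NA_real_,
                     level)
    attr(out, "boot_seed") <- seed
    return(out)
  }
  est <- mode_estimate(re$ratio, w, bandwidth_factor)
  se <- boot_se(pair, seed, n_boot, function(b, wb) {
    mode_estimate(b, wb, bandwidth_factor)
  })
  pval <- 2 * stats::pnorm(-abs(est / se))
  out <- mr_result("weighted_mode", nrow(re), est, se, pval, level)
  attr(out, "boot_seed") <- seed
  out
}

mode_estimate <- function(b, w, phi = 1) {
  if (max(b) - min(b) < 1e-12) return(b[1L])
  w <- w / sum(w)
  s_mad <- weighted_mad_(b, w)
  s_sd <- weighted_sd_(b, w)
  scales <- c(s_sd, s_mad)
  scales <- scales[scales > 0]
  s <- 0.9 * min(scales) * length(b)^(-1 / 5)
  h <- phi * s
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512L)
  dens <- colSums(w * stats::dnorm(outer(b, grid, "-") / h))
  grid[which.max(dens)]
}

# Parametric bootstrap over instrument-level effects (two-sample normal
# resampling of beta_x and beta_y), re-running `estimator(ratios, weights)`.
boot_se <- function(pair, seed, n_boot, estimator) {
  with_seed(seed, {
    k <- nrow(pair)
    ests <- vapply(seq_len(n_boot), function(j) {
      bx <- stats::rnorm(k, pair$beta_x, pair$se_x)
      by <- stats::rnorm(k, pair$beta_y, pair$se_y)
      ok <- bx != 0
      estimator(by[ok] / bx[ok], (bx[ok] / pair$se_y[ok])^2)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_i (ratio_i - beta_ivw)^2)` with `w_i = 1/se_ratio_i^2`;
#' p-value from chi-square with `k-1` degrees of freedom. P-values below
#' 0.05 indicate heterogeneity among instrument-level estimates.
#'
#' @param ratios per-SNP ratio estimates.
#' @param se_ratios their standard errors.
#' @param beta_ivw the pooled inverse-variance-weighted estimate.
#' @return List with `q_stat` and `q_pval`.
#' @export
cochran_q <- function(ratios, se_ratios, beta_ivw) {
  stopifnot(length(ratios) >= 2L, length(ratios) == length(se_ratios))
  w <- 1 / se_ratios^2
  q <- sum(w * (ratios - beta_ivw)^2)
  list(q_stat = q,
       q_pval = stats::pchisq(q, df = length(ratios) - 1, lower.tail = FALSE))
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW model omitting each SNP in turn and flags SNPs whose
#' omission flips the sign of the estimate or moves it by more than
#' `se_mult` times the full-model standard error.
#'
#' @param pair a `harmonized_pair` with at least 3 SNPs.
#' @param se_mult flagging multiple of the full-model se (default 2).
#' @return Data frame with one row per omitted SNP (`snp_id`, `beta`, `se`,
#'   `pval`, `flagged`) plus the full-model estimate in attributes.
#' @export
leave_one_out <- function(pair, se_mult = 2) {
  stopifnot(inherits(pair, "harmonized_pair"))
  k <- nrow(pair)
  if (k < 3L) stop("leave_one_out() requires >= 3 SNPs", call. = FALSE)
  full <- ivw(pair)
  rows <- lapply(seq_len(k), function(i) {
    fit <- ivw(pair_subset(pair, -i))
    data.frame(snp_id = pair$snp_id[i], beta = fit$beta, se = fit$se,
               pval = fit$pval)
  })
  out <- do.call(rbind, rows)
  sign_flip <- sign(out$beta) != sign(full$beta) & full$beta != 0
  out$flagged <- sign_flip | abs(out$beta - full$beta) > se_mult * full$se
  attr(out, "full") <- full
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; output order matches
#' input order. P-values must lie in (0, 1].
#'
#' @param pvals raw p-values.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Odds ratio and confidence interval from a log-odds estimate
#'
#' `or = exp(beta)` with bounds `exp(beta +/- z * se)`; the geometric mean
#' of the bounds equals the odds ratio.
#'
#' @param beta log-odds effect(s).
#' @param se standard error(s), `>= 0`.
#' @param level confidence level (default 0.95).
#' @return Data frame with columns `or`, `ci_low`, `ci_high` (vectorized).
#' @export
or_ci <- function(beta, se, level = 0.95) {
  stopifnot(all(se >= 0))
  z <- z975(level)
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}

#' Reconstruct a log-odds estimate from printed OR confidence bounds
#'
#' The inverse of [or_ci()] on the bounds alone: the point estimate is the
#' geometric mean of the bounds and the standard error is the log-bound
#' half-width divided by the normal quantile. Useful for checking the
#' internal consistency of published odds-ratio tables.
#'
#' @param ci_low,ci_high printed confidence bounds (`0 < ci_low < ci_high`).
#' @param level confidence level of the printed interval.
#' @return Data frame with columns `or`, `beta`, `se`.
#' @export
or_from_ci <- function(ci_low, ci_high, level = 0.95) {
  stopifnot(all(ci_low > 0), all(ci_high > ci_low))
  z <- z975(level)
  beta <- (log(ci_low) + log(ci_high)) / 2
  data.frame(or = exp(beta), beta = beta,
             se = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Two-sided p-value from a printed odds ratio and confidence interval
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 z)` and
#' `p = 2 Phi(-|log(or)|/se)`.
#'
#' @param or odds ratio; must lie strictly between the bounds.
#' @param ci_low,ci_high confidence bounds.
#' @param level confidence level of the printed interval.
#' @return Two-sided normal p-value(s).
#' @export
p_from_or_ci <- function(or, ci_low, ci_high, level = 0.95) {
  if (!all(0 < ci_low & ci_low < or & or < ci_high)) {
    stop("p_from_or_ci(): bounds must bracket the odds ratio", call. = FALSE)
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * z975(level))
  2 * stats::pnorm(-abs(log(or)) / se)
}

#' Run every applicable MR estimator on a harmonized pair
#'
#' One SNP: Wald ratio. Two SNPs: IVW. Three or more: IVW, MR-Egger,
#' weighted median and weighted mode. The attribute `sign_concordant`
#' records whether all computed estimates share a sign — the screen's
#' direction-consistency requirement.
#'
#' @param pair a `harmonized_pair`.
#' @param seed bootstrap seed for the median/mode estimators.
#' @param n_boot bootstrap draws.
#' @param level confidence level.
#' @return Data frame of stacked MR results, attribute `sign_concordant`.
#' @export
mr_all_methods <- function(pair, seed = 1L, n_boot = 1000, level = 0.95) {
  k <- nrow(pair)
  res <- if (k == 1L) {
    wald_ratio(pair, level)
  } else if (k == 2L) {
    ivw(pair, level)
  } else {
    rbind(ivw(pair, level), mr_egger(pair, level),
          weighted_median(pair, n_boot, seed, level),
          weighted_mode(pair, 1, n_boot, seed, level))
  }
  attr(res, "sign_concordant") <- length(unique(sign(res$beta))) == 1L
  res
}
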