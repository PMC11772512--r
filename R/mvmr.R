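#' @title Multivariable MR and coefficient-product mediation
#' @description Multivariable IVW regresses per-SNP outcome effects jointly
#'   on several exposures' effects to estimate each exposure's direct
#'   effect conditional on the others (here: dissecting hypertension,
#'   systolic and diastolic blood pressure). The coefficient-product method
#'   then decomposes a total effect into the indirect path through a
#'   mediator and the direct remainder.
#' @name mvmr-mediation
NULL

#' Multivariable inverse-variance-weighted regression
#'
#' Weighted least squares of outcome effects on the per-SNP exposure-effect
#' matrix without intercept, weights `1/se^2`, with multiplicative
#' over-dispersion inflation floored at 1. Instruments must be
#' pre-harmonized to a single effect-allele frame and must outnumber the
#' exposures.
#'
#' @param outcome_beta per-SNP outcome effects.
#' @param outcome_se per-SNP outcome standard errors.
#' @param exposure_beta matrix (SNP x exposure) of exposure effects.
#' @param exposure_names exposure labels (default: column names).
#' @return An object of class `mvmr_result`: data frame `estimates`
#'   (`exposure`, `beta`, `se`, `pval`, `conditional_f`), and `n_snp`.
#'   `conditional_f` is reported `NA`: a faithful conditional F-statistic
#'   needs instrument-correlation information that summary-level inputs do
#'   not carry.
#' @export
mvmr_ivw <- function(outcome_beta, outcome_se, exposure_beta,
                     exposure_names = colnames(exposure_beta)) {
  x <- as.matrix(exposure_beta)
  k <- nrow(x)
  p <- ncol(x)
  if (is.null(exposure_names)) exposure_names <- paste0("exposure", seq_len(p))
  stopifnot(length(outcome_beta) == k, length(outcome_se) == k,
            all(outcome_se > 0))
  if (k <= p) {
    stop("mvmr_ivw(): need more SNPs than exposures (", k, " SNPs, ", p,
         " exposures)", call. = FALSE)
  }
  qrx <- qr(x)
  if (qrx$rank < p) {
    offending <- exposure_names[qrx$pivot[(qrx$rank + 1):p]]
    stop("mvmr_ivw(): collinear exposure column(s): ",
         paste(offending, collapse = ", "), call. = FALSE)
  }
  w <- 1 / outcome_se^2
  fit <- stats::lm(outcome_beta ~ 0 + x, weights = w)
  sm <- summary(fit)
  disp <- min(1, sm$sigma)  # dispersion >= 1 (never deflate)
  beta <- unname(sm$coefficients[, "Estimate"])
  se <- unname(sm$coefficients[, "Std. Error"]) / disp
  pval <- 2 * stats::pnorm(-abs(beta / se))
  structure(
    list(estimates = data.frame(exposure = exposure_names, beta = beta,
                                se = se, pval = pval,
                                conditional_f = NA_real_),
         n_snp = k),
    class = "mvmr_result"
  )
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d exposures, %d SNPs\n",
              nrow(x$estimates), x$n_snp))
  print(x$estimates)
  invisible(x)
}

as_effect <- function(x, what) {
  if (is.list(x)) x <- c(x$beta, x$se)
  x <- as.numeric(x)
  if (length(x) != 2L || is.na(x[1]) || is.na(x[2]) || x[2] < 0) {
    stop("mediation_product(): '", what,
         "' must be c(beta, se) with se >= 0", call. = FALSE)
  }
  x
}

#' Coefficient-product mediation decomposition
#'
#' `indirect = b(exposure->mediator) * b(mediator->outcome)` with the
#' delta-method standard error `sqrt(b1^2 s2^2 + b2^2 s1^2)`;
#' `direct = total - indirect`; `proportion = indirect/total`. Proportions
#' outside [0, 1] are legitimate (inconsistent mediation, e.g. a mediated
#' share above 100%) and are reported verbatim with a qualitative flag.
#' All three inputs must be on consistently oriented log-odds or SD scales.
#'
#' @param total total exposure->outcome effect as `c(beta, se)` (or a list
#'   with `beta`/`se`).
#' @param exp_to_med exposure->mediator effect, same form.
#' @param med_to_out mediator->outcome effect (typically adjusted for the
#'   exposure via [mvmr_ivw()]; a univariable estimate is equally
#'   accepted), same form.
#' @return One-row data frame: `total`, `indirect`, `direct`, `proportion`,
#'   `se_indirect`, `flag` (`"consistent"`, `"inconsistent"` or
#'   `"undefined"`).
#' @export
mediation_product <- function(total, exp_to_med, med_to_out) {
  tot <- as_effect(total, "total")
  a <- as_effect(exp_to_med, "exp_to_med")
  b <- as_effect(med_to_out, "med_to_out")
  indirect <- a[1] * b[1]
  se_ind <- sqrt(a[1]^2 * b[2]^2 + b[1]^2 * a[2]^2)
  direct <- tot[1] - indirect
  if (tot[1] == 0) {
    proportion <- NA_real_
    flag <- "undefined"
  } else {
    proportion <- indirect / tot[1]
    flag <- if (proportion < 0 || proportion > 1) "inconsistent" else "consistent"
  }
  data.frame(total = tot[1], indirect = indirect, direct = direct,
             proportion = proportion, se_indirect = se_ind, flag = flag)
}

#' Estimate a mediation decomposition from three harmonized pairs
#'
#' Convenience wrapper: fits IVW (or the Wald ratio for single-instrument
#' pairs) to the exposure->outcome, exposure->mediator and
#' mediator->outcome pairs and feeds the estimates to
#' [mediation_product()].
#'
#' @param total_pair,exp_to_med_pair,med_to_out_pair `harmonized_pair`
#'   objects.
#' @return As [mediation_product()].
#' @export
estimate_mediation <- function(total_pair, exp_to_med_pair, med_to_out_pair) {
  fit <- function(pair) {
    res <- if (nrow(pair) == 1L) wald_ratio(pair) else ivw(pair)
    c(res$beta, res$se)
  }
  mediation_product(fit(total_pair), fit(exp_to_med_pair),
                    fit(med_to_out_pair))
}
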