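#' @title Bayesian colocalization via Wakefield approximate Bayes factors
#' @description For a region shared by two traits, five hypotheses are
#'   weighed: H0 no association with either trait; H1/H2 association with
#'   one trait only; H3 association with both traits through two distinct
#'   causal variants; H4 association with both through the same variant.
#'   Per-SNP evidence comes from Wakefield's closed-form approximate Bayes
#'   factor; hypothesis weights are accumulated in log space so extreme
#'   z-scores do not overflow.
#' @name coloc
NULL

#' Per-SNP prior probabilities for colocalization
#'
#' @param p1 prior that a SNP is associated with trait 1 only
#'   (default 1e-4).
#' @param p2 prior for trait 2 only (default 1e-4).
#' @param p12 prior for both traits (default 1e-5).
#' @return An object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, p12 > 0, p12 < 1,
            p1 + p2 + p12 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2` and `z = beta/se`:
#' `lABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W))`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), `> 0`.
#' @param prior_sd prior standard deviation of the true effect.
#' @return Log Bayes factor(s) against the null (vectorized).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(v / (v + w)) + z2 * w / (v + w))
}

default_prior_sd <- function(trait_type) {
  # conventional effect-scale priors: SD units for quantitative traits,
  # log-odds for binary
  switch(trait_type, quantitative = 0.15, binary = 0.2)
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' The two sets are intersected on SNP identifier (the approximate Bayes
#' factor depends on the squared z-score, so allele orientation does not
#' matter). With per-SNP Bayes factors `BF1_i`, `BF2_i` and priors
#' `p1, p2, p12`, the unnormalized hypothesis weights are `H0 = 1`,
#' `H1 = p1 * sum(BF1)`, `H2 = p2 * sum(BF2)`,
#' `H3 = p1 p2 * (sum(BF1) sum(BF2) - sum(BF1*BF2))` (distinct causal
#' SNPs) and `H4 = p12 * sum(BF1*BF2)`; everything is computed with
#' log-sum-exp. A single-SNP region has `PPH3 = 0` by construction.
#'
#' @param trait1,trait2 `sumstats` objects for the region.
#' @param priors a [coloc_priors()] object.
#' @param prior_sd1,prior_sd2 per-trait effect priors; default 0.15 for
#'   quantitative traits and 0.2 (log-odds) for binary.
#' @return An object of class `coloc_result`: `region`, `n_snps`, `pp`
#'   (named vector `PPH0..PPH4` summing to 1), `top_shared_snp`.
#' @export
coloc_posteriors <- function(trait1, trait2, priors = coloc_priors(),
                             prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(trait1, "sumstats"), inherits(trait2, "sumstats"),
            inherits(priors, "coloc_priors"))
  sd1 <- prior_sd1 %||% default_prior_sd(trait1$trait_type)
  sd2 <- prior_sd2 %||% default_prior_sd(trait2$trait_type)
  shared <- intersect(trait1$snps$snp_id, trait2$snps$snp_id)
  if (length(shared) < 1L) {
    stop("coloc_posteriors(): no shared SNPs between the two traits",
         call. = FALSE)
  }
  d1 <- trait1$snps[match(shared, trait1$snps$snp_id), ]
  d2 <- trait2$snps[match(shared, trait2$snps$snp_id), ]
  l1 <- wakefield_labf(d1$beta, d1$se, sd1)
  l2 <- wakefield_labf(d2$beta, d2$se, sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(
    PPH0 = 0,
    PPH1 = log(priors$p1) + s1,
    PPH2 = log(priors$p2) + s2,
    PPH3 = log(priors$p1) + log(priors$p2) + s1 + s2 +
      log1p(-exp(min(s12 - s1 - s2, 0))),
    PPH4 = log(priors$p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  structure(
    list(region = trait1$region, n_snps = length(shared), pp = pp,
         top_shared_snp = shared[which.max(l1 + l2)]),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs; top shared SNP %s\n", x$n_snps,
              x$top_shared_snp))
  print(round(x$pp, 4))
  invisible(x)
}

#' Apply the region-level colocalization decision rule
#'
#' A region passes when `PPH4 > pph4_min` (shared causal variant) or
#' `PPH3 + PPH4 > pph34_min` (association with both traits, allowing
#' linkage). The rule that fired is recorded rather than merged.
#'
#' @param result a `coloc_result`.
#' @param pph4_min threshold on PPH4 (default 0.75).
#' @param pph34_min threshold on PPH3 + PPH4 (default 0.8).
#' @return List with `pass` and `rule_fired` (`"pph4"`, `"pph3+pph4"` or
#'   `NA`).
#' @export
coloc_pass <- function(result, pph4_min = 0.75, pph34_min = 0.8) {
  pp <- result$pp
  if (pp[["PPH4"]] > pph4_min) {
    list(pass = TRUE, rule_fired = "pph4")
  } else if (pp[["PPH3"]] + pp[["PPH4"]] > pph34_min) {
    list(pass = TRUE, rule_fired = "pph3+pph4")
  } else {
    list(pass = FALSE, rule_fired = NA_character_)
  }
}
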