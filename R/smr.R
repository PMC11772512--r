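#' @title Summary-data-based Mendelian randomization and the HEIDI test
#' @description SMR combines the top cis-eQTL association with the disease
#'   GWAS association at the same SNP into a single causal test of gene
#'   expression on the outcome. HEIDI (heterogeneity in dependent
#'   instruments) then asks whether surrounding SNPs in LD with the top SNP
#'   give the same expression-to-outcome ratio: a single shared causal
#'   variant (vertical pleiotropy) predicts identical ratios, two distinct
#'   causal variants in LD (linkage) predicts heterogeneous ones.
#' @name smr-heidi
NULL

#' SMR test at the top cis-eQTL
#'
#' With eQTL z-score `z_x = beta_x/se_x` and GWAS z-score `z_y = beta_y/se_y`
#' at the same SNP and allele orientation:
#' `b_smr = beta_y/beta_x`, `t_smr = z_x^2 z_y^2 / (z_x^2 + z_y^2)`
#' (chi-square, 1 df), and the delta-method standard error
#' `se_smr = |b_smr| sqrt(1/z_x^2 + 1/z_y^2)`.
#'
#' @param eqtl_top list or one-row data frame with `beta`, `se` (and
#'   optionally `snp_id`) for the top eQTL.
#' @param gwas_at_top same-SNP GWAS record (`beta`, `se`), aligned to the
#'   same effect allele.
#' @return List with `top_snp`, `b_smr`, `se_smr`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(eqtl_top, gwas_at_top) {
  bx <- as.numeric(eqtl_top$beta)
  sx <- as.numeric(eqtl_top$se)
  by <- as.numeric(gwas_at_top$beta)
  sy <- as.numeric(gwas_at_top$se)
  stopifnot(length(bx) == 1L, sx > 0, sy > 0)
  if (bx == 0) stop("smr_test(): eQTL effect is zero, ratio undefined",
                    call. = FALSE)
  zx2 <- (bx / sx)^2
  zy2 <- (by / sy)^2
  t_smr <- if (zy2 == 0) 0 else zx2 * zy2 / (zx2 + zy2)
  b_smr <- by / bx
  # |b|*sqrt(1/zx^2 + 1/zy^2) -> sy/|bx| as beta_y -> 0
  se_smr <- if (by == 0) sy / abs(bx)
            else abs(b_smr) * sqrt(1 / zx2 + 1 / zy2)
  list(top_snp = as.character(eqtl_top$snp_id %||% NA_character_),
       b_smr = b_smr, se_smr = se_smr, t_smr = t_smr,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Selects up to `m_max` SNPs (besides the top SNP) whose eQTL p-value is
#' below `p_eqtl_max` and whose squared correlation with the top SNP lies in
#' `r2_range`, computes each SNP's SMR ratio difference to the top SNP with
#' delta-method variances and LD-derived covariances, and tests the sum of
#' squared standardized differences against a Satterthwaite moment-matched
#' chi-square for the correlated quadratic form. Small p-values indicate
#' linkage (distinct causal variants) rather than a single shared variant.
#'
#' @param eqtl,gwas `sumstats` objects covering the region.
#' @param ld `ld_matrix` covering the region.
#' @param top_snp identifier of the top cis-eQTL.
#' @param p_eqtl_max eQTL inclusion threshold (default 1.57e-3).
#' @param r2_range admissible squared correlation to the top SNP
#'   (default `c(0.05, 0.9)`).
#' @param m_max,m_min maximum/minimum number of test SNPs (defaults 20, 3).
#' @return List with `p_heidi` (NA when fewer than `m_min` SNPs are
#'   eligible), `m_used`, and `reason` when missing.
#' @export
heidi_test <- function(eqtl, gwas, ld, top_snp, p_eqtl_max = 1.57e-3,
                       r2_range = c(0.05, 0.9), m_max = 20, m_min = 3) {
  stopifnot(inherits(ld, "ld_matrix"))
  pair <- harmonize(eqtl, gwas)
  if (!top_snp %in% pair$snp_id) {
    return(list(p_heidi = NA_real_, m_used = 0L,
                reason = "top SNP lost in harmonization"))
  }
  if (!top_snp %in% ld$snp_ids) {
    stop("heidi_test(): top SNP absent from LD matrix", call. = FALSE)
  }
  in_ld <- pair$snp_id %in% ld$snp_ids
  pair <- pair_subset(pair, in_ld)
  ep <- eqtl$snps$pval[match(pair$snp_id, eqtl$snps$snp_id)]
  r_top <- ld$r[pair$snp_id, top_snp]
  r2_top <- r_top^2
  cand <- which(pair$snp_id != top_snp & ep < p_eqtl_max &
                  r2_top >= r2_range[1] & r2_top <= r2_range[2])
  if (length(cand) < m_min) {
    return(list(p_heidi = NA_real_, m_used = length(cand),
                reason = sprintf("only %d eligible SNPs (minimum %d)",
                                 length(cand), m_min)))
  }
  if (length(cand) > m_max) cand <- cand[order(ep[cand])][seq_len(m_max)]

  sel <- c(which(pair$snp_id == top_snp), cand)
  bx <- pair$beta_x[sel]
  sx <- pair$se_x[sel]
  by <- pair$beta_y[sel]
  sy <- pair$se_y[sel]
  b <- by / bx
  R <- ld$r[pair$snp_id[sel], pair$snp_id[sel]]
  # delta-method covariance of the ratio estimates; eQTL and GWAS samples
  # are independent, SNP-SNP correlation enters through R
  C <- R * (outer(sy / bx, sy / bx) + outer(b * sx / bx, b * sx / bx))
  m <- length(cand)
  d <- b[-1L] - b[1L]
  Cd <- C[-1L, -1L, drop = FALSE] -
    matrix(C[-1L, 1L], m, m) - matrix(C[1L, -1L], m, m, byrow = TRUE) +
    C[1L, 1L]
  v <- diag(Cd)
  t_stat <- sum(d^2 / v)
  Rd <- Cd / sqrt(outer(v, v))
  # Satterthwaite: match mean m and variance 2*sum(Rd^2) of the correlated
  # chi-square sum with a scaled chi-square
  vt <- 2 * sum(Rd^2)
  scale <- vt / (2 * m)
  df <- 2 * m^2 / vt
  list(p_heidi = stats::pchisq(t_stat / scale, df = df, lower.tail = FALSE),
       m_used = m, reason = NULL)
}
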