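# Small in-code fixtures and independent oracles shared across test files.

snp_df <- function(n, chrom = "1", pos = NULL, ea = "A", oa = "G",
                   eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-9,
                   nn = 10000) {
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)), chrom = chrom,
    pos = pos %||% (1000L + 1000L * seq_len(n)),
    effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
    eaf = rep_len(eaf, n), beta = rep_len(beta, n), se = rep_len(se, n),
    pval = rep_len(pval, n), n = rep_len(nn, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_pair <- function(beta_x, se_x, beta_y, se_y,
                      ids = sprintf("rs%03d", seq_along(beta_x))) {
  harmonized_pair(
    data.frame(snp_id = ids, beta_x = beta_x, se_x = se_x,
               beta_y = beta_y, se_y = se_y),
    exposure_id = "X", outcome_id = "Y"
  )
}

# pair whose per-SNP ratios and ratio standard errors are exactly as given
pair_from_ratios <- function(ratios, se_ratios, se_x = 1e-6) {
  make_pair(beta_x = rep(1, length(ratios)), se_x = se_x,
            beta_y = ratios, se_y = se_ratios)
}

ar1_ld <- function(ids, rho = 0.9) {
  n <- length(ids)
  ld_matrix(rho^abs(outer(seq_len(n), seq_len(n), "-")), ids)
}

# instrument-level null (no causal effect) with known outcome se
null_pair <- function(k = 20, se_y = 0.02) {
  bx <- stats::runif(k, 0.08, 0.12)
  make_pair(bx, 1e-8, stats::rnorm(k, 0, se_y), se_y)
}

# --- independent oracles ---------------------------------------------------

# greedy clumping re-run: set-based, removal by explicit filtering
clump_oracle <- function(df, r, r2_max, window_kb) {
  kept <- character()
  cand <- df[order(df$pval, df$pos, df$snp_id), , drop = FALSE]
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept <- c(kept, top$snp_id)
    r2v <- r[cand$snp_id, top$snp_id]^2
    within <- abs(cand$pos - top$pos) <= window_kb * 1000
    cand <- cand[!(within & r2v >= r2_max) & cand$snp_id != top$snp_id, ,
                 drop = FALSE]
  }
  sort(kept)
}

# weighted percentile by explicit midpoint interpolation (no approx())
weighted_median_oracle <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(x[1])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  i <- max(which(s < 0.5))
  x[i] + (x[i + 1] - x[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# exhaustive enumeration of single-causal-variant configurations in linear
# space: (i, j) with i the causal SNP for trait 1 (0 = none), j for trait 2
coloc_enum_oracle <- function(bf1, bf2, p1, p2, p12) {
  n <- length(bf1)
  h <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (i in seq_len(n)) h["H1"] <- h["H1"] + p1 * bf1[i]
  for (j in seq_len(n)) h["H2"] <- h["H2"] + p2 * bf2[j]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        h["H4"] <- h["H4"] + p12 * bf1[i] * bf2[j]
      } else {
        h["H3"] <- h["H3"] + p1 * p2 * bf1[i] * bf2[j]
      }
    }
  }
  h / sum(h)
}
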