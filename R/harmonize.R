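#' @title Allele harmonization and greedy LD clumping
#' @name harmonize-clump
NULL

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Construct a harmonized exposure/outcome pair
#'
#' Usually produced by [harmonize()]; the constructor is exported so that
#' simulators and tests can build aligned pairs directly.
#'
#' @param data data frame with columns `snp_id`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y` (exposure and outcome effects on a shared
#'   effect-allele frame).
#' @param exposure_id,outcome_id trait identifiers.
#' @param dropped data frame `(snp_id, reason)` of SNPs removed during
#'   harmonization; reasons are `missing_in_outcome`, `palindromic` or
#'   `allele_mismatch`.
#' @return An object of class `harmonized_pair` (a data frame).
#' @export
harmonized_pair <- function(data, exposure_id, outcome_id,
                            dropped = data.frame(snp_id = character(),
                                                 reason = character())) {
  data <- as.data.frame(data)
  need <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(data))) {
    stop("harmonized pair needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(data$se_x > 0), all(data$se_y > 0))
  ok <- dropped$reason %in% c("missing_in_outcome", "palindromic",
                              "allele_mismatch")
  if (!all(ok)) stop("unknown drop reason: ", dropped$reason[!ok][1], call. = FALSE)
  rownames(data) <- NULL
  structure(data[need],
            exposure_id = exposure_id, outcome_id = outcome_id,
            dropped = dropped, class = c("harmonized_pair", "data.frame"))
}

pair_subset <- function(pair, idx) {
  harmonized_pair(as.data.frame(pair)[idx, , drop = FALSE],
                  attr(pair, "exposure_id"), attr(pair, "outcome_id"))
}

#' Harmonize exposure and outcome summary statistics to a shared allele frame
#'
#' SNPs are matched by identifier. When the outcome's effect allele equals
#' the exposure's other allele (and vice versa) the outcome effect sign is
#' flipped. A/T and C/G SNPs are dropped as palindromic unconditionally (no
#' frequency-based rescue), SNPs absent from the outcome are dropped as
#' `missing_in_outcome`, and SNPs whose alleles cannot be reconciled as
#' `allele_mismatch`. Harmonizing an already-aligned pair is the identity.
#'
#' @param exposure,outcome `sumstats` objects.
#' @return A `harmonized_pair`; its `dropped` attribute records removals.
#' @export
harmonize <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$snps
  ou <- outcome$snps
  dropped <- data.frame(snp_id = character(), reason = character())
  drop <- function(ids, reason) {
    if (length(ids)) {
      dropped <<- rbind(dropped, data.frame(snp_id = ids, reason = reason))
    }
  }

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  drop(ex$snp_id[pal], "palindromic")
  ex <- ex[!pal, , drop = FALSE]

  m <- match(ex$snp_id, ou$snp_id)
  drop(ex$snp_id[is.na(m)], "missing_in_outcome")
  keep <- !is.na(m)
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[m[keep], , drop = FALSE]

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  flipped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  drop(ex$snp_id[!(same | flipped)], "allele_mismatch")
  ex <- ex[same | flipped, , drop = FALSE]
  beta_y <- ifelse(flipped[same | flipped], -ou$beta[same | flipped],
                   ou$beta[same | flipped])
  se_y <- ou$se[same | flipped]

  if (nrow(ex) == 0L) {
    stop("harmonize(): no SNPs shared between '", exposure$trait_id,
         "' and '", outcome$trait_id, "' after allele reconciliation",
         call. = FALSE)
  }
  harmonized_pair(
    data.frame(snp_id = ex$snp_id, beta_x = ex$beta, se_x = ex$se,
               beta_y = beta_y, se_y = se_y),
    exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
    dropped = dropped
  )
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly retains the remaining SNP with the smallest p-value and removes
#' every other remaining SNP with squared correlation `>= r2_max` to it that
#' lies within `window_kb` of it. The window bounds the search: a SNP beyond
#' the window is never removed on account of the index SNP. Ties on p-value
#' are broken by smaller position, then lexicographic SNP id, so the result
#' is independent of input row order. Output is sorted by position.
#'
#' @param stats a `sumstats` object; every SNP must appear in `ld`.
#' @param ld an `ld_matrix` covering the SNPs.
#' @param r2_max squared-correlation ceiling (default 0.001).
#' @param window_kb search window in kilobases (default 10,000).
#' @return A `sumstats` object containing the retained records.
#' @export
clump <- function(stats, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(stats, "sumstats"), inherits(ld, "ld_matrix"))
  df <- stats$snps
  missing <- setdiff(df$snp_id, ld$snp_ids)
  if (length(missing)) {
    stop("clump(): SNP(s) absent from LD matrix: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  if (nrow(df) == 0L) return(stats)
  ord <- order(df$pval, df$pos, df$snp_id)
  df <- df[ord, , drop = FALSE]
  r2 <- ld$r[df$snp_id, df$snp_id, drop = FALSE]^2
  active <- rep(TRUE, nrow(df))
  keep <- logical(nrow(df))
  while (any(active)) {
    i <- which(active)[1L]
    keep[i] <- TRUE
    within <- abs(df$pos - df$pos[i]) <= window_kb * 1000
    active <- active & !(within & r2[, i] >= r2_max)
    active[i] <- FALSE
  }
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$pos, out$snp_id), , drop = FALSE]
  sumstats(out, trait_id = stats$trait_id, trait_type = stats$trait_type,
           region = stats$region)
}
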