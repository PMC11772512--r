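#' @title Summary-statistic simulator with known ground truth
#' @description Generates paired cis-eQTL and case-control GWAS summary
#'   statistics for one LD region under the five colocalization scenarios,
#'   so every stage of the screen can be tested offline against latent
#'   truth. Effects are parameterized on the standardized-genotype scale:
#'   a causal cis-eQTL explaining a fraction `eqtl_var_explained` of
#'   expression variance has standardized effect `sqrt(eqtl_var_explained)`,
#'   and under the shared-variant scenario the outcome's log-odds effect at
#'   that variant is `causal_effect` (log-OR per SD expression) times the
#'   expression effect. Marginal effects are LD-propagated, observed
#'   z-scores are the true z-scores plus LD-correlated standard normal
#'   noise, and standard errors follow the usual large-sample forms
#'   (`1/sqrt(2p(1-p)n)` for a standardized quantitative trait and
#'   `1/sqrt(2p(1-p) N v(1-v))` for a case-control trait with case
#'   fraction `v`).
#' @name synthetic-data
NULL

#' Scenario configuration for the region simulator
#'
#' Default sample sizes mirror the study conditions the screen targets:
#' 31,684 individuals for blood cis-eQTLs and 7495 cases / 71,934 controls
#' for the binary outcome.
#'
#' @param scenario one of `"H0"` (no association), `"H1"` (eQTL only),
#'   `"H2"` (outcome only), `"H3"` (distinct causal variants in LD),
#'   `"H4"` (one shared causal variant).
#' @param n_snps number of SNPs in the region.
#' @param ld_model `"ar1"` (correlation `ld_rho^|i-j|`) or `"block"`
#'   (within-block correlation `ld_rho`, zero across blocks).
#' @param ld_rho LD decay/plateau parameter (default 0.9).
#' @param block_size block width for the block model.
#' @param maf_range uniform range for minor allele frequencies.
#' @param n_eqtl eQTL sample size.
#' @param n_cases,n_controls outcome case-control counts.
#' @param eqtl_var_explained expression variance explained by the causal
#'   cis variant, in [0, 1).
#' @param causal_effect log-OR on the outcome per SD of expression.
#' @param pleiotropy_sd SD of independent per-SNP direct effects on the
#'   outcome (standardized-genotype log-odds scale); 0 for none.
#' @param h3_r2 target squared correlation between the two causal variants
#'   under `"H3"` (AR(1) model; under the block model the second variant is
#'   the adjacent in-block SNP, so its r2 is `ld_rho^2`).
#' @param chrom,start_pos,spacing_bp genomic coordinates of the region.
#' @param id_prefix prefix for generated SNP identifiers.
#' @param seed mandatory simulation seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("H4", "H0", "H1", "H2", "H3"),
                            n_snps = 200, ld_model = c("ar1", "block"),
                            ld_rho = 0.9, block_size = 25,
                            maf_range = c(0.05, 0.5), n_eqtl = 31684,
                            n_cases = 7495, n_controls = 71934,
                            eqtl_var_explained = 0.02, causal_effect = 0.3,
                            pleiotropy_sd = 0, h3_r2 = 0.25, chrom = "1",
                            start_pos = 1e6, spacing_bp = 2500,
                            id_prefix = "", seed) {
  if (missing(seed)) stop("scenario_config(): seed is mandatory", call. = FALSE)
  scenario <- match.arg(scenario)
  ld_model <- match.arg(ld_model)
  stopifnot(n_snps >= 1, ld_rho > 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_eqtl > 2, n_cases > 0, n_controls > 0,
            h3_r2 > 0, h3_r2 < 1, spacing_bp >= 1)
  if (eqtl_var_explained < 0 || eqtl_var_explained >= 1) {
    stop("scenario_config(): eqtl_var_explained must lie in [0, 1)",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "scenario_config")
}

build_ld <- function(n, model, rho, block_size) {
  if (model == "ar1") {
    rho^abs(outer(seq_len(n), seq_len(n), "-"))
  } else {
    blk <- (seq_len(n) - 1L) %/% block_size
    r <- ifelse(outer(blk, blk, "=="), rho, 0)
    diag(r) <- 1
    r
  }
}

# non-palindromic allele pairs only, so harmonization never silently thins
# the simulated region
ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate paired eQTL/GWAS summary statistics for one region
#'
#' See [scenario_config()] for the generative model. About 30% of the GWAS
#' records are emitted on the swapped allele frame (with the effect sign
#' flipped) so that harmonization is exercised; the truth record is
#' unaffected.
#'
#' @param config a `scenario_config`.
#' @return List with `eqtl` (`sumstats`, quantitative), `gwas` (`sumstats`,
#'   binary), `ld` (`ld_matrix`) and `truth` (causal indices, true
#'   standardized effects and z-scores, scenario).
#' @export
simulate_region <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_snps
    maf <- stats::runif(n, cf$maf_range[1], cf$maf_range[2])
    pos <- as.integer(cf$start_pos + (seq_len(n) - 1L) * cf$spacing_bp)
    ids <- sprintf("%srs%05d", cf$id_prefix, seq_len(n))
    R <- build_ld(n, cf$ld_model, cf$ld_rho, cf$block_size)

    c1 <- ceiling(n / 2)
    c2 <- NA_integer_
    b_std <- sqrt(cf$eqtl_var_explained)
    g_std <- cf$causal_effect * b_std
    gamma_e <- numeric(n)
    gamma_g <- numeric(n)
    if (cf$scenario %in% c("H1", "H3", "H4")) gamma_e[c1] <- b_std
    if (cf$scenario == "H2") gamma_g[c1] <- g_std
    if (cf$scenario == "H4") gamma_g[c1] <- g_std
    if (cf$scenario == "H3") {
      d <- if (cf$ld_model == "ar1") {
        max(1L, as.integer(round(log(sqrt(cf$h3_r2)) / log(cf$ld_rho))))
      } else {
        1L
      }
      c2 <- min(n, c1 + d)
      gamma_g[c2] <- g_std
    }
    if (cf$pleiotropy_sd > 0) {
      gamma_g <- gamma_g + stats::rnorm(n, 0, cf$pleiotropy_sd)
    }

    marg_e <- as.vector(R %*% gamma_e)
    marg_g <- as.vector(R %*% gamma_g)
    denom <- sqrt(2 * maf * (1 - maf))
    se_e <- 1 / (denom * sqrt(cf$n_eqtl))
    n_g <- cf$n_cases + cf$n_controls
    v <- cf$n_cases / n_g
    se_g <- 1 / (denom * sqrt(n_g * v * (1 - v)))
    z_e_true <- marg_e * sqrt(cf$n_eqtl)
    z_g_true <- marg_g * sqrt(n_g * v * (1 - v))

    L <- chol(R)
    z_e <- z_e_true + as.vector(crossprod(L, stats::rnorm(n)))
    z_g <- z_g_true + as.vector(crossprod(L, stats::rnorm(n)))

    alleles <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), n, replace = TRUE), ,
                            drop = FALSE]
    region <- list(chrom = cf$chrom, start = min(pos), end = max(pos))
    base <- data.frame(snp_id = ids, chrom = cf$chrom, pos = pos,
                       effect_allele = alleles[, 1],
                       other_allele = alleles[, 2], eaf = maf)

    eqtl_df <- base
    eqtl_df$beta <- z_e * se_e
    eqtl_df$se <- se_e
    eqtl_df$pval <- 2 * stats::pnorm(-abs(z_e))
    eqtl_df$n <- cf$n_eqtl

    gwas_df <- base
    gwas_df$beta <- z_g * se_g
    gwas_df$se <- se_g
    gwas_df$pval <- 2 * stats::pnorm(-abs(z_g))
    gwas_df$n <- n_g
    # swap ~30% of GWAS records onto the opposite allele frame
    swap <- stats::runif(n) < 0.3
    tmp <- gwas_df$effect_allele[swap]
    gwas_df$effect_allele[swap] <- gwas_df$other_allele[swap]
    gwas_df$other_allele[swap] <- tmp
    gwas_df$beta[swap] <- -gwas_df$beta[swap]
    gwas_df$eaf[swap] <- 1 - gwas_df$eaf[swap]

    list(
      eqtl = sumstats(eqtl_df, trait_id = paste0(cf$id_prefix, "expression"),
                      trait_type = "quantitative", region = region),
      gwas = sumstats(gwas_df, trait_id = paste0(cf$id_prefix, "outcome"),
                      trait_type = "binary", region = region),
      ld = ld_matrix(R, ids),
      truth = list(scenario = cf$scenario, causal_eqtl = c1,
                   causal_gwas = if (cf$scenario == "H3") c2
                                 else if (cf$scenario %in% c("H2", "H4")) c1
                                 else NA_integer_,
                   snp_ids = ids, gamma_e = gamma_e, gamma_g = gamma_g,
                   z_e_true = z_e_true, z_g_true = z_g_true,
                   ratio_true = if (cf$scenario == "H4") cf$causal_effect
                                else NA_real_)
    )
  })
}

#' Simulate instrument-level tables for a mediation chain
#'
#' Builds three ready-to-analyse [harmonized_pair()] tables for a chain
#' X -> M -> Y with an additional direct X -> Y path: the exposure's
#' instruments measured against Y (total effect `direct + a*b`) and
#' against M (effect `a`), plus an independent instrument set for the
#' mediator measured against Y (effect `b`). The truth record carries the
#' implied proportion mediated `a*b / (direct + a*b)`.
#'
#' @param effect_xm exposure->mediator effect `a`.
#' @param effect_my mediator->outcome effect `b`.
#' @param effect_direct direct exposure->outcome effect.
#' @param n_instruments instruments per exposure (default 30).
#' @param se_exposure standard error of instrument-exposure effects
#'   (default 0.004).
#' @param se_assoc standard error of instrument-outcome/mediator effects
#'   (default 0.02).
#' @param seed mandatory seed.
#' @return List with `total`, `exp_to_med`, `med_to_out`
#'   (`harmonized_pair` objects) and `truth`.
#' @export
simulate_mediation_chain <- function(effect_xm, effect_my, effect_direct,
                                     n_instruments = 30, se_exposure = 0.004,
                                     se_assoc = 0.02, seed) {
  if (missing(seed)) stop("simulate_mediation_chain(): seed is mandatory",
                          call. = FALSE)
  with_seed(seed, {
    k <- n_instruments
    total_true <- effect_direct + effect_xm * effect_my
    bx_true <- stats::runif(k, 0.05, 0.2) * sample(c(-1, 1), k, replace = TRUE)
    bx <- stats::rnorm(k, bx_true, se_exposure)
    by_tot <- stats::rnorm(k, total_true * bx_true, se_assoc)
    bm <- stats::rnorm(k, effect_xm * bx_true, se_assoc)
    bm2_true <- stats::runif(k, 0.05, 0.2) * sample(c(-1, 1), k, replace = TRUE)
    bm2 <- stats::rnorm(k, bm2_true, se_exposure)
    by2 <- stats::rnorm(k, effect_my * bm2_true, se_assoc)
    mk_pair <- function(prefix, beta_x, se_x, beta_y, se_y, xid, yid) {
      harmonized_pair(
        data.frame(snp_id = sprintf("%s%02d", prefix, seq_len(k)),
                   beta_x = beta_x, se_x = se_x, beta_y = beta_y,
                   se_y = se_y),
        exposure_id = xid, outcome_id = yid)
    }
    list(
      total = mk_pair("xi", bx, se_exposure, by_tot, se_assoc, "X", "Y"),
      exp_to_med = mk_pair("xi", bx, se_exposure, bm, se_assoc, "X", "M"),
      med_to_out = mk_pair("mi", bm2, se_exposure, by2, se_assoc, "M", "Y"),
      truth = list(total = total_true, indirect = effect_xm * effect_my,
                   direct = effect_direct,
                   proportion = if (total_true == 0) NA_real_
                                else effect_xm * effect_my / total_true)
    )
  })
}

#' Simulate a multi-gene screening benchmark with planted targets
#'
#' Builds the full input bundle for [run_cascade()]: per-gene cis regions
#' (one eQTL dataset), a genome-wide outcome GWAS assembled from the
#' per-gene regions, per-gene LD matrices, a gene annotation table and a
#' druggable-gene list. `n_true` genes are planted as real targets (shared
#' causal variant, expression->outcome effect, in the druggable list);
#' the remaining genes cycle through decoy scenarios: no signal (H0),
#' eQTL-only (H1), outcome-only (H2) and linkage (H3, two causal variants
#' in LD). H0/H1/H2 decoys are placed in the druggable list so that
#' recovery rests on the statistics; H3 decoys are kept out of it because
#' the region-level decision rule deliberately admits linkage.
#'
#' @param n_genes total genes (default 20).
#' @param n_true planted targets (default 3).
#' @param n_snps SNPs per gene region.
#' @param causal_effect expression->outcome log-OR for planted targets and
#'   outcome-signal decoys (default 0.6).
#' @param seed mandatory seed.
#' @param dataset_id,outcome_id labels for the simulated eQTL dataset and
#'   outcome.
#' @return List with `eqtl`, `gwas`, `ld`, `annotations`, `druggable`,
#'   `truth` (a data frame of gene-level scenarios) ready for
#'   [run_cascade()].
#' @export
simulate_benchmark <- function(n_genes = 20, n_true = 3, n_snps = 200,
                               causal_effect = 0.6, seed,
                               dataset_id = "synth_eqtl",
                               outcome_id = "synth_outcome") {
  if (missing(seed)) stop("simulate_benchmark(): seed is mandatory",
                          call. = FALSE)
  stopifnot(n_true >= 0, n_true <= n_genes)
  decoys <- c("H0", "H1", "H2", "H3")
  scen <- c(rep("H4", n_true),
            rep_len(decoys, n_genes - n_true))
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  eqtl_sets <- list()
  ld_store <- list()
  gwas_parts <- list()
  ann <- list()
  for (g in seq_len(n_genes)) {
    cfg <- scenario_config(
      scenario = scen[g], n_snps = n_snps, causal_effect = causal_effect,
      chrom = as.character(g), id_prefix = sprintf("g%02d_", g),
      seed = seed + 1000L * g
    )
    sim <- simulate_region(cfg)
    sim$eqtl$trait_id <- genes[g]
    eqtl_sets[[genes[g]]] <- sim$eqtl
    ld_store[[genes[g]]] <- sim$ld
    gwas_parts[[g]] <- sim$gwas$snps
    tss <- sim$eqtl$snps$pos[ceiling(n_snps / 2)]
    ann[[g]] <- data.frame(gene_id = genes[g], symbol = genes[g],
                           chrom = as.character(g), tss = tss, strand = "+")
  }
  gwas <- sumstats(do.call(rbind, gwas_parts), trait_id = outcome_id,
                   trait_type = "binary")
  druggable_symbols <- genes[scen %in% c("H4", "H0", "H1", "H2")]
  list(
    eqtl = stats::setNames(list(eqtl_sets), dataset_id),
    gwas = stats::setNames(list(gwas), outcome_id),
    ld = ld_store,
    annotations = do.call(rbind, ann),
    druggable = druggable_list(druggable_symbols, source_tag = "synthetic"),
    truth = data.frame(gene_id = genes, scenario = scen,
                       planted = scen == "H4")
  )
}
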