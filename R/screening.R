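#' @title The end-to-end druggable-gene screening cascade
#' @description Four stages, each gating the next: (1) SMR at the top
#'   cis-eQTL with the HEIDI linkage diagnostic reported alongside;
#'   (2) two-sample MR on clumped cis instruments with FDR control,
#'   direction consistency across estimators and an Egger-intercept
#'   pleiotropy gate; (3) Bayesian colocalization of the gene's region
#'   with the outcome; (4) membership in a druggable-genome list. Every
#'   gene attempted gets a ledger row carrying stage-by-stage provenance;
#'   a failed stage short-circuits later stages to "not evaluated".
#' @name screening
NULL

#' Construct a druggable-gene list
#'
#' @param symbols gene symbols; upper-cased and de-duplicated.
#' @param source_tag provenance label for the list.
#' @return An object of class `druggable_list`.
#' @export
druggable_list <- function(symbols, source_tag = "user") {
  symbols <- unique(toupper(trimws(as.character(symbols))))
  symbols <- symbols[symbols != ""]
  if (length(symbols) == 0L) {
    stop("druggable_list(): empty gene list", call. = FALSE)
  }
  structure(list(symbols = symbols, source_tag = source_tag),
            class = "druggable_list")
}

#' @export
print.druggable_list <- function(x, ...) {
  cat(sprintf("<druggable_list> %d symbols (%s)\n", length(x$symbols),
              x$source_tag))
  invisible(x)
}

#' Load a druggable-gene list from a flat file
#'
#' Accepts one symbol per line, or a two-column tab-separated file
#' `(symbol, category)` with a header, in which case only rows whose
#' category is `druggable genome` (case-insensitive) are kept — mirroring
#' a drug-gene interaction database export consumed locally.
#'
#' @param path file path.
#' @param source_tag provenance label (default: the file name).
#' @return A `druggable_list`.
#' @export
load_druggable_list <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("cannot read druggable list: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) stop("druggable list is empty: ", path,
                                call. = FALSE)
  if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t")
    header <- tolower(trimws(parts[[1]]))
    body <- parts[-1]
    symbols <- vapply(body, `[`, character(1), 1L)
    if (length(header) >= 2L) {
      category <- tolower(trimws(vapply(body, `[`, character(1), 2L)))
      symbols <- symbols[category == "druggable genome"]
    }
  } else {
    symbols <- lines
  }
  if (length(symbols) == 0L) {
    stop("druggable list has no 'druggable genome' entries: ", path,
         call. = FALSE)
  }
  druggable_list(symbols, source_tag)
}

#' Membership test on a druggable-gene list (case-insensitive)
#' @param list a `druggable_list`.
#' @param symbols gene symbols to look up.
#' @return Logical vector.
#' @export
is_druggable <- function(list, symbols) {
  stopifnot(inherits(list, "druggable_list"))
  toupper(trimws(symbols)) %in% list$symbols
}

#' Default thresholds for the screening cascade
#'
#' All thresholds are the screen's standard operating values: SMR p < 0.05;
#' cis-instrument selection at p < 5e-8 within +/-100 kb of the TSS with
#' MAF > 0.01, clumped at r2 < 0.001 within 10,000 kb; FDR 0.05 on the MR
#' stage with an Egger-intercept gate (p >= 0.05) when more than two
#' instruments are available; colocalization priors 1e-4/1e-4/1e-5 over a
#' gene +/-500 kb region with pass rule PPH4 > 0.75 or PPH3+PPH4 > 0.8.
#' HEIDI is reported, not gated, unless `heidi_p_min` is set.
#'
#' @param ... named overrides of any default.
#' @return Named list of thresholds.
#' @export
cascade_config <- function(...) {
  cfg <- list(
    smr_p_max = 0.05,
    eqtl_p_max = 5e-8,
    maf_min = 0.01,
    tss_window_kb = 100,
    clump_r2 = 0.001,
    clump_window_kb = 10000,
    fdr_alpha = 0.05,
    egger_intercept_alpha = 0.05,
    heidi_p_min = NULL,          # NULL: report-only
    coloc_window_kb = 500,
    pph4_min = 0.75,
    pph34_min = 0.8,
    coloc_priors = coloc_priors(),
    n_boot = 1000,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("cascade_config(): unknown option(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  cfg
}

#' Provenance manifest for a cascade run
#'
#' @param config cascade configuration list.
#' @param inputs named character vector/list describing the inputs.
#' @return List with the package version, seed, a digest of the
#'   configuration, and the input description; identical manifests imply
#'   identical outputs.
#' @export
run_manifest <- function(config, inputs = character()) {
  cfg_string <- paste(utils::capture.output(utils::str(config)),
                      collapse = "\n")
  list(package = "targetmr",
       version = as.character(utils::packageVersion("targetmr")),
       seed = config$seed,
       config_digest = sprintf("%08x", sum(utf8ToInt(cfg_string) *
                                             seq_along(utf8ToInt(cfg_string)))
                               %% 0xFFFFFFFF),
       inputs = inputs)
}

# Stage 1-3 statistics for one gene x dataset x outcome (no FDR yet; the
# family-level adjustment happens in run_cascade once all genes are seen).
screen_gene_stages <- function(eqtl, gwas, ld, gene, config) {
  out <- list(
    gene_id = gene$gene_id, symbol = gene$symbol,
    p_smr = NA_real_, b_smr = NA_real_, top_snp = NA_character_,
    p_heidi = NA_real_, m_heidi = NA_integer_, stage1_pass = NA,
    n_snp = NA_integer_, method = NA_character_, beta = NA_real_,
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    pval_mr = NA_real_, q_pval = NA_real_, egger_intercept_pval = NA_real_,
    sign_concordant = NA, egger_ok = NA,
    pph3 = NA_real_, pph4 = NA_real_, coloc_rule = NA_character_,
    status = NA_character_
  )

  # ---- stage 1: SMR at the top cis-eQTL -------------------------------
  pair <- tryCatch(harmonize(eqtl, gwas), error = function(e) NULL)
  if (is.null(pair)) {
    out$status <- "untestable_stage1"
    return(out)
  }
  ep <- eqtl$snps[match(pair$snp_id, eqtl$snps$snp_id), ]
  maf <- pmin(ep$eaf, 1 - ep$eaf)
  elig <- which(!is.na(ep$pval) & ep$pval < config$eqtl_p_max &
                  !is.na(maf) & maf > config$maf_min)
  if (length(elig) == 0L) {
    out$status <- "untestable_stage1"
    return(out)
  }
  top <- elig[order(ep$pval[elig], ep$pos[elig], ep$snp_id[elig])][1L]
  smr <- smr_test(
    list(snp_id = pair$snp_id[top], beta = pair$beta_x[top],
         se = pair$se_x[top]),
    list(beta = pair$beta_y[top], se = pair$se_y[top])
  )
  out$p_smr <- smr$p_smr
  out$b_smr <- smr$b_smr
  out$top_snp <- pair$snp_id[top]
  if (!is.null(ld)) {
    heidi <- heidi_test(eqtl, gwas, ld, top_snp = pair$snp_id[top])
    out$p_heidi <- heidi$p_heidi
    out$m_heidi <- heidi$m_used
  }
  stage1 <- smr$p_smr < config$smr_p_max
  if (stage1 && !is.null(config$heidi_p_min) && !is.na(out$p_heidi)) {
    stage1 <- out$p_heidi >= config$heidi_p_min
  }
  out$stage1_pass <- stage1
  if (!stage1) {
    out$status <- "fail_stage1_smr"
    return(out)
  }

  # ---- stage 2: two-sample MR on clumped cis instruments --------------
  if (is.null(ld)) {
    # clumping cannot run without an LD reference for the region
    out$status <- "untestable_stage2"
    return(out)
  }
  inst <- select_cis_instruments(
    eqtl, gene, ld, p_max = config$eqtl_p_max,
    window_kb = config$tss_window_kb, maf_min = config$maf_min,
    clump_r2 = config$clump_r2, clump_window_kb = config$clump_window_kb
  )
  if (n_snps(inst$snps) == 0L) {
    out$status <- "untestable_stage2"
    return(out)
  }
  inst_pair <- tryCatch(harmonize(inst$snps, gwas), error = function(e) NULL)
  if (is.null(inst_pair) || nrow(inst_pair) == 0L) {
    out$status <- "untestable_stage2"
    return(out)
  }
  mres <- mr_all_methods(inst_pair, seed = config$seed,
                         n_boot = config$n_boot)
  primary <- mres[1L, ]  # wald (k=1) or ivw (k>=2)
  out$n_snp <- primary$n_snp
  out$method <- primary$method
  out$beta <- primary$beta
  out$or <- primary$or
  out$ci_low <- primary$ci_low
  out$ci_high <- primary$ci_high
  out$pval_mr <- primary$pval
  out$q_pval <- primary$q_pval
  out$sign_concordant <- attr(mres, "sign_concordant")
  egger_row <- mres[mres$method == "egger", ]
  out$egger_intercept_pval <- if (nrow(egger_row)) {
    egger_row$egger_intercept_pval
  } else {
    NA_real_
  }
  # Egger-intercept gate applies only when more than two instruments exist
  out$egger_ok <- if (primary$n_snp > 2L) {
    out$egger_intercept_pval >= config$egger_intercept_alpha
  } else {
    TRUE
  }
  out
}

#' Run the four-stage druggable-gene screening cascade
#'
#' @param eqtl named list: dataset id -> named list of gene id ->
#'   `sumstats` (the gene's cis-eQTL region, quantitative).
#' @param gwas named list: outcome id -> `sumstats` (binary).
#' @param ld either one `ld_matrix` for all genes or a named list keyed by
#'   gene id; a gene whose region has no LD reference is marked untestable
#'   and the run continues.
#' @param annotations gene annotation data frame (`gene_id`, `symbol`,
#'   `chrom`, `tss`, `strand`), as from [read_gene_annotation()].
#' @param druggable a `druggable_list`.
#' @param config thresholds from [cascade_config()].
#' @return A data frame with one screening record per gene x dataset x
#'   outcome attempted: stage-by-stage statistics, pass flags (`NA` when a
#'   stage was not evaluated because an earlier one failed), the failing
#'   stage in `status`, and `final`. The FDR family is one
#'   Benjamini-Hochberg adjustment per (outcome, dataset) pair. A
#'   `run_manifest()` is attached as an attribute.
#' @export
run_cascade <- function(eqtl, gwas, ld, annotations, druggable,
                        config = cascade_config()) {
  stopifnot(inherits(druggable, "druggable_list"),
            is.list(eqtl), is.list(gwas))
  ld_for <- function(gene_id) {
    if (inherits(ld, "ld_matrix")) return(ld)
    ld[[gene_id]]
  }
  all_rows <- list()
  for (ds in names(eqtl)) {
    for (oc in names(gwas)) {
      fam <- lapply(names(eqtl[[ds]]), function(g) {
        gene <- annotations[annotations$gene_id == g, , drop = FALSE]
        if (nrow(gene) != 1L) {
          stop("run_cascade(): no (unique) annotation for gene ", g,
               call. = FALSE)
        }
        screen_gene_stages(eqtl[[ds]][[g]], gwas[[oc]], ld_for(g),
                           as.list(gene[1L, ]), config)
      })
      fam <- lapply(fam, function(r) {
        r$dataset_id <- ds
        r$outcome_id <- oc
        r$pfdr <- NA_real_
        r$stage2_pass <- NA
        r$stage3_pass <- NA
        r$in_druggable <- NA
        r$stage4_pass <- NA
        r$final <- FALSE
        r
      })
      # family-level FDR over genes whose MR stage produced a p-value
      tested <- which(vapply(fam, function(r) !is.na(r$pval_mr), logical(1)))
      if (length(tested)) {
        adj <- bh_fdr(vapply(fam[tested], `[[`, numeric(1), "pval_mr"))
        for (j in seq_along(tested)) fam[[tested[j]]]$pfdr <- adj[j]
      }
      for (i in seq_along(fam)) {
        r <- fam[[i]]
        if (!is.na(r$status)) {  # already failed/untestable at stage 1-2
          all_rows[[length(all_rows) + 1L]] <- r
          next
        }
        r$stage2_pass <- r$pfdr < config$fdr_alpha &&
          isTRUE(r$sign_concordant) && isTRUE(r$egger_ok)
        if (!r$stage2_pass) {
          r$status <- "fail_stage2_mr"
          all_rows[[length(all_rows) + 1L]] <- r
          next
        }
        # ---- stage 3: colocalization over the gene +/- 500 kb region ---
        gene <- annotations[annotations$gene_id == r$gene_id, , drop = FALSE]
        gene_eqtl <- eqtl[[ds]][[r$gene_id]]
        in_window <- abs(gene_eqtl$snps$pos - gene$tss) <=
          config$coloc_window_kb * 1000
        coloc_in <- sumstats(gene_eqtl$snps[in_window, , drop = FALSE],
                             gene_eqtl$trait_id, gene_eqtl$trait_type,
                             gene_eqtl$region)
        cres <- tryCatch(
          coloc_posteriors(coloc_in, gwas[[oc]], config$coloc_priors),
          error = function(e) NULL
        )
        if (is.null(cres)) {
          r$status <- "untestable_stage3"
          all_rows[[length(all_rows) + 1L]] <- r
          next
        }
        r$pph3 <- cres$pp[["PPH3"]]
        r$pph4 <- cres$pp[["PPH4"]]
        rule <- coloc_pass(cres, config$pph4_min, config$pph34_min)
        r$coloc_rule <- rule$rule_fired
        r$stage3_pass <- rule$pass
        if (!rule$pass) {
          r$status <- "fail_stage3_coloc"
          all_rows[[length(all_rows) + 1L]] <- r
          next
        }
        # ---- stage 4: druggability ------------------------------------
        r$in_druggable <- is_druggable(druggable, r$symbol)
        r$stage4_pass <- r$in_druggable
        if (!r$stage4_pass) {
          r$status <- "fail_stage4_druggable"
        } else {
          r$status <- "pass"
          r$final <- TRUE
        }
        all_rows[[length(all_rows) + 1L]] <- r
      }
    }
  }
  cols <- c("gene_id", "symbol", "dataset_id", "outcome_id",
            "p_smr", "b_smr", "top_snp", "p_heidi", "m_heidi", "stage1_pass",
            "n_snp", "method", "beta", "or", "ci_low", "ci_high", "pval_mr",
            "pfdr", "q_pval", "egger_intercept_pval", "sign_concordant",
            "egger_ok", "stage2_pass", "pph3", "pph4", "coloc_rule",
            "stage3_pass", "in_druggable", "stage4_pass", "final", "status")
  ledger <- do.call(rbind, lapply(all_rows, function(r) {
    as.data.frame(r[cols])
  }))
  rownames(ledger) <- NULL
  attr(ledger, "manifest") <- run_manifest(
    config, inputs = c(datasets = paste(names(eqtl), collapse = ","),
                       outcomes = paste(names(gwas), collapse = ","),
                       druggable = druggable$source_tag)
  )
  ledger
}
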