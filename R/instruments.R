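#' @title cis-eQTL instrument selection and instrument strength
#' @description Instruments for a gene are cis-eQTL SNPs passing a
#'   genome-wide significance threshold within a window of the transcription
#'   start site and a minor-allele-frequency floor, thinned to independence
#'   by greedy LD clumping. Per-instrument variance explained and
#'   F-statistics quantify instrument strength.
#' @name instruments
NULL

#' Read a gene annotation table (BED-like)
#'
#' Tab-separated columns `chrom, tss-1, tss, gene_id, symbol, strand` with a
#' header; the two coordinate columns follow the BED 0-based half-open
#' convention, so the feature `[tss-1, tss)` is the 1-based TSS base.
#'
#' @param path file path.
#' @return Data frame with columns `gene_id`, `symbol`, `chrom`, `tss`
#'   (1-based), `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("chrom", "start", "end", "gene_id", "symbol", "strand")
  if (!all(need %in% names(raw))) {
    stop("gene annotation needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  start <- as.integer(raw$start)
  end <- as.integer(raw$end)
  if (any(end != start + 1L)) {
    stop("gene annotation: end must equal start + 1 (single-base TSS feature)",
         call. = FALSE)
  }
  if (any(end < 1L)) stop("gene annotation: tss must be positive", call. = FALSE)
  if (!all(raw$strand %in% c("+", "-"))) {
    stop("gene annotation: strand must be '+' or '-'", call. = FALSE)
  }
  data.frame(gene_id = raw$gene_id, symbol = raw$symbol, chrom = raw$chrom,
             tss = end, strand = raw$strand)
}

#' Per-SNP variance explained and F-statistic
#'
#' Uses the standardized-trait approximation `r2 = 2*eaf*(1-eaf)*beta^2`
#' (capped just below 1) and `F = (n-2)*r2/(1-r2)`. Requires the effect
#' allele frequency and sample size; errors if either is missing.
#'
#' @param beta per-allele effect (SD units of the exposure).
#' @param eaf effect-allele frequency in (0,1).
#' @param n sample size (> 2).
#' @return A data frame with columns `r2` and `f_stat` (vectorized).
#' @export
instrument_strength <- function(beta, eaf, n) {
  if (any(is.na(eaf)) || any(is.na(n))) {
    stop("instrument strength unavailable: eaf and n are required",
         call. = FALSE)
  }
  stopifnot(all(eaf > 0 & eaf < 1), all(n > 2))
  r2 <- pmin(2 * eaf * (1 - eaf) * beta^2, 1 - 1e-12)
  f <- (n - 2) * r2 / (1 - r2)
  data.frame(r2 = r2, f_stat = f)
}

#' Select cis-eQTL instruments for a gene
#'
#' Filters the supplied cis-eQTL records to `pval < p_max`, position within
#' `window_kb` of the gene's TSS and minor allele frequency above `maf_min`
#' (records without an allele frequency cannot clear the MAF floor and are
#' excluded), then clumps the survivors at `clump_r2` within
#' `clump_window_kb`. Per-survivor strength statistics are attached.
#'
#' An empty survivor set is returned as an empty instrument set rather than
#' an error, so the screen can record the gene as untestable.
#'
#' @param eqtl `sumstats` for the gene's cis region (quantitative).
#' @param gene one-row gene annotation (`gene_id`, `symbol`, `chrom`, `tss`).
#' @param ld `ld_matrix` covering the candidate SNPs.
#' @param p_max eQTL p-value threshold (default 5e-8).
#' @param window_kb TSS window in kb (default 100, i.e. +/-100 kb).
#' @param maf_min minor-allele-frequency floor (default 0.01, exclusive).
#' @param clump_r2,clump_window_kb clumping parameters (defaults 0.001 and
#'   10,000 kb).
#' @param dataset_id label for the eQTL dataset.
#' @return An object of class `instrument_set` with fields `gene_id`,
#'   `dataset_id`, `snps` (a `sumstats`), `f_stats`, `r2`.
#' @export
select_cis_instruments <- function(eqtl, gene, ld, p_max = 5e-8,
                                   window_kb = 100, maf_min = 0.01,
                                   clump_r2 = 0.001, clump_window_kb = 10000,
                                   dataset_id = eqtl$trait_id) {
  stopifnot(inherits(eqtl, "sumstats"))
  df <- eqtl$snps
  maf <- pmin(df$eaf, 1 - df$eaf)
  keep <- !is.na(df$pval) & df$pval < p_max &
    abs(df$pos - gene$tss) <= window_kb * 1000 &
    !is.na(maf) & maf > maf_min
  df <- df[keep, , drop = FALSE]
  empty <- function() {
    structure(list(gene_id = gene$gene_id, dataset_id = dataset_id,
                   snps = sumstats(df[0, , drop = FALSE], eqtl$trait_id,
                                   eqtl$trait_type, eqtl$region),
                   f_stats = numeric(), r2 = numeric()),
              class = "instrument_set")
  }
  if (nrow(df) == 0L) return(empty())
  filtered <- sumstats(df, eqtl$trait_id, eqtl$trait_type, eqtl$region)
  clumped <- clump(filtered, ld, r2_max = clump_r2,
                   window_kb = clump_window_kb)
  strength <- instrument_strength(clumped$snps$beta, clumped$snps$eaf,
                                  clumped$snps$n)
  structure(list(gene_id = gene$gene_id, dataset_id = dataset_id,
                 snps = clumped, f_stats = strength$f_stat,
                 r2 = strength$r2),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> gene %s (%s): %d instrument(s)\n",
              x$gene_id, x$dataset_id, n_snps(x$snps)))
  invisible(x)
}
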