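#' @title Summary-statistic containers and delimited-text I/O
#' @description Per-SNP association records (one trait, usually one cis
#'   region) are the universal currency of every stage of the screen. A
#'   `sumstats` object wraps a validated data frame of SNP records together
#'   with a trait identifier, the trait type (binary traits carry log-odds
#'   effects, quantitative traits SD-unit effects) and an optional region.
#' @name sumstats-io
NULL

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated summary-statistic set
#'
#' @param data data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA`.
#' @param trait_id identifier for the trait (gene, disease, risk factor).
#' @param trait_type `"binary"` (effects are log-odds ratios) or
#'   `"quantitative"` (effects per SD).
#' @param region optional `list(chrom =, start =, end =)`, a 1-based closed
#'   interval; all records must lie on its chromosome.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(data, trait_id, trait_type = c("binary", "quantitative"),
                     region = NULL) {
  trait_type <- match.arg(trait_type)
  data <- as.data.frame(data)
  missing_cols <- setdiff(SUMSTAT_COLS, names(data))
  if (length(missing_cols)) {
    stop("summary statistics missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[SUMSTAT_COLS]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  rownames(data) <- NULL
  problems <- validate_snp_records(data, region)
  if (nrow(problems)) {
    stop("invalid summary statistics for '", trait_id, "':\n  ",
         paste(format_problems(problems, "row"), collapse = "\n  "),
         call. = FALSE)
  }
  structure(
    list(trait_id = as.character(trait_id), trait_type = trait_type,
         snps = data, region = region),
    class = "sumstats"
  )
}

# Returns a data frame (row, msg) of validation failures; zero rows if clean
validate_snp_records <- function(data, region = NULL) {
  problems <- data.frame(row = integer(), msg = character())
  bad <- function(rows, msg) {
    if (length(rows)) {
      problems <<- rbind(problems, data.frame(row = rows, msg = msg))
    }
  }
  bad(which(is.na(data$snp_id) | data$snp_id == ""), "missing snp_id")
  bad(which(is.na(data$pos) | data$pos < 1L), "pos must be a positive integer")
  bad(which(!data$effect_allele %in% VALID_ALLELES),
      "effect_allele not one of A/C/G/T")
  bad(which(!data$other_allele %in% VALID_ALLELES),
      "other_allele not one of A/C/G/T")
  bad(which(data$effect_allele == data$other_allele),
      "effect_allele equals other_allele")
  bad(which(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1)),
      "eaf outside (0,1)")
  bad(which(is.na(data$beta)), "missing beta")
  bad(which(is.na(data$se) | data$se <= 0), "se must be > 0")
  bad(which(is.na(data$pval) | data$pval <= 0 | data$pval > 1),
      "pval outside (0,1]")
  bad(which(!is.na(data$n) & data$n <= 0), "n must be > 0")
  dup <- duplicated(data$snp_id)
  bad(which(dup), "duplicate snp_id (duplicates are rejected, not merged)")
  if (!is.null(region)) {
    bad(which(data$chrom != as.character(region$chrom)),
        sprintf("chrom differs from region chromosome %s", region$chrom))
  }
  problems
}

format_problems <- function(problems, label = "row", offset = 0L) {
  by_msg <- split(problems$row + offset, problems$msg)
  vapply(names(by_msg), function(m) {
    sprintf("%s %s: %s", label, paste(sort(by_msg[[m]]), collapse = ","), m)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d SNPs", x$trait_id,
              x$trait_type, nrow(x$snps)))
  if (!is.null(x$region)) {
    cat(sprintf(", region %s:%s-%s", x$region$chrom, x$region$start,
                x$region$end))
  }
  cat("\n")
  invisible(x)
}

#' Number of SNP records in a summary-statistic set
#' @param x a `sumstats` object.
#' @export
n_snps <- function(x) nrow(x$snps)

#' Read summary statistics from tab-separated text
#'
#' Expects a header naming the columns `snp_id, chrom, pos, effect_allele,
#' other_allele, eaf, beta, se, pval, n`; `.` marks a missing value.
#' Malformed rows are reported with their file line numbers (header = line 1).
#'
#' @param path file path.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param trait_id trait identifier; defaults to the file name.
#' @param region optional region (see [sumstats()]).
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, trait_type, trait_id = NULL, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(SUMSTAT_COLS, names(raw))
  if (length(missing_cols)) {
    stop("format error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[SUMSTAT_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    unparsed <- which(!is.na(raw[[col]]) & is.na(val))
    if (length(unparsed)) {
      stop(sprintf("format error in %s: non-numeric '%s' on line %s", path,
                   col, paste(unparsed + 1L, collapse = ",")), call. = FALSE)
    }
    raw[[col]] <- val
  }
  problems <- validate_snp_records(raw, region)
  if (nrow(problems)) {
    # file line numbers: header occupies line 1, first record line 2
    stop("validation error in ", path, ":\n  ",
         paste(format_problems(problems, "line", offset = 1L),
               collapse = "\n  "), call. = FALSE)
  }
  sumstats(raw, trait_id = trait_id %||% basename(path),
           trait_type = trait_type, region = region)
}

#' Write summary statistics as tab-separated text
#'
#' Inverse of [read_sumstats()]: `read_sumstats(write_sumstats(x, f))`
#' reproduces `x` field for field. Missing values are written as `.`.
#'
#' @param x a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  out <- x$snps
  # full precision so the round trip is exact
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(out[[col]]), ".",
                         formatC(out[[col]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Construct an LD correlation matrix
#'
#' @param r square numeric matrix of signed correlations in `[-1, 1]`;
#'   symmetric (tolerance 1e-8) with unit diagonal.
#' @param snp_ids SNP identifiers; defaults to `rownames(r)`.
#' @return An object of class `ld_matrix` with fields `snp_ids` and `r`.
#' @export
ld_matrix <- function(r, snp_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(snp_ids)) stop("snp_ids required (no rownames on r)", call. = FALSE)
  snp_ids <- as.character(snp_ids)
  if (nrow(r) != ncol(r) || nrow(r) != length(snp_ids)) {
    stop("LD matrix dimension does not match number of snp_ids", call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) stop("duplicate snp_ids in LD matrix", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix not symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1", call. = FALSE)
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must lie in [-1,1]", call. = FALSE)
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r = r), class = "ld_matrix")
}

#' Read an LD matrix from square tab-separated text
#'
#' First row and first column carry the SNP identifiers.
#' @param path file path.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  m <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  ld_matrix(as.matrix(m))
}

#' Write an LD matrix as square tab-separated text
#' @param ld an `ld_matrix` object.
#' @param path output file path.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  out <- data.frame(snp_id = ld$snp_ids,
                    formatC(ld$r, digits = 17, format = "g"),
                    check.names = FALSE)
  names(out) <- c("snp_id", ld$snp_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d SNPs\n", length(x$snp_ids)))
  invisible(x)
}
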