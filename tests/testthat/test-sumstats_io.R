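test_that("well-formed files round-trip field for field", {
  df <- snp_df(3)
  x <- sumstats(df, "trait", "binary")
  expect_equal(n_snps(x), 3L)

  set.seed(401)
  big <- snp_df(100)
  big$eaf <- runif(100, 0.01, 0.99)
  big$beta <- rnorm(100, 0, 0.3)
  big$se <- runif(100, 0.001, 0.1)
  big$pval <- runif(100)
  big$eaf[7] <- NA  # '.' round-trip
  big$n[13] <- NA
  x <- sumstats(big, "big", "quantitative")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, f)
  y <- read_sumstats(f, "quantitative", trait_id = "big")
  expect_equal(y$snps, x$snps, tolerance = 1e-12)
  expect_identical(y$trait_type, "quantitative")
})

test_that("validation errors name the offending rows and lines", {
  df <- snp_df(3)
  df$se[2] <- 0
  expect_error(sumstats(df, "t", "binary"), "row 2.*se must be > 0")

  f <- withr::local_tempfile(fileext = ".tsv")
  good <- snp_df(3)
  good$pval[2] <- 0  # invalid on file line 3 (header is line 1)
  write.table(good, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f, "binary"), "line 3.*pval")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  bad <- snp_df(2)[, -1]  # drop snp_id column
  write.table(bad, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(f2, "binary"), "missing required column")

  dup <- snp_df(2)
  dup$snp_id <- c("rs1", "rs1")
  expect_error(sumstats(dup, "t", "binary"), "duplicate")
})

test_that("harmonize flips swapped alleles and drops palindromic/missing SNPs", {
  ex <- sumstats(snp_df(1, ea = "A", oa = "G", beta = 0.1), "X", "quantitative")
  ou_df <- snp_df(1, ea = "G", oa = "A", beta = 0.05)
  ou <- sumstats(ou_df, "Y", "binary")
  pair <- harmonize(ex, ou)
  expect_equal(pair$beta_y, -0.05)

  # palindromic exposure SNP dropped unconditionally
  ex2 <- sumstats(snp_df(2, ea = c("A", "A"), oa = c("T", "G")), "X",
                  "quantitative")
  ou2 <- sumstats(snp_df(2, ea = c("A", "A"), oa = c("T", "G")), "Y", "binary")
  pair2 <- harmonize(ex2, ou2)
  expect_equal(nrow(pair2), 1L)
  dropped <- attr(pair2, "dropped")
  expect_equal(dropped$reason[dropped$snp_id == "rs001"], "palindromic")

  # missing-in-outcome bookkeeping on simulated sets
  ex3 <- sumstats(snp_df(10), "X", "quantitative")
  ou3_df <- snp_df(10)[1:8, ]
  ou3 <- sumstats(ou3_df, "Y", "binary")
  pair3 <- harmonize(ex3, ou3)
  expect_equal(nrow(pair3), 8L)
  d3 <- attr(pair3, "dropped")
  expect_setequal(d3$snp_id, c("rs009", "rs010"))
  expect_true(all(d3$reason == "missing_in_outcome"))

  # allele mismatch
  ex4 <- sumstats(snp_df(1, ea = "A", oa = "G"), "X", "quantitative")
  ou4 <- sumstats(snp_df(1, ea = "A", oa = "C"), "Y", "binary")
  expect_error(harmonize(ex4, ou4), "no SNPs shared")

  # empty intersection errors
  ex5 <- sumstats(snp_df(2), "X", "quantitative")
  ou5_df <- snp_df(2)
  ou5_df$snp_id <- c("zz1", "zz2")
  expect_error(harmonize(ex5, sumstats(ou5_df, "Y", "binary")),
               "no SNPs shared")
})

test_that("harmonization is idempotent on an aligned pair", {
  sim <- simulate_region(scenario_config("H4", n_snps = 40, seed = 5))
  pair <- harmonize(sim$eqtl, sim$gwas)
  # rebuild the outcome on the exposure's allele frame and re-harmonize
  aligned <- sim$gwas$snps
  m <- match(sim$eqtl$snps$snp_id, aligned$snp_id)
  flip <- aligned$effect_allele[m] != sim$eqtl$snps$effect_allele
  aligned$beta[m][flip] <- -aligned$beta[m][flip]
  ea <- aligned$effect_allele[m][flip]
  aligned$effect_allele[m][flip] <- aligned$other_allele[m][flip]
  aligned$other_allele[m][flip] <- ea
  pair2 <- harmonize(sim$eqtl, sumstats(aligned, "Y", "binary"))
  expect_equal(pair2$beta_y, pair$beta_y, tolerance = 1e-12)
  expect_equal(nrow(attr(pair2, "dropped")), 0L)
})

test_that("LD matrices validate and round-trip", {
  ids <- sprintf("rs%03d", 1:4)
  ld <- ar1_ld(ids, 0.8)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, f)
  ld2 <- read_ld_matrix(f)
  expect_equal(ld2$r, ld$r, tolerance = 1e-12)

  bad <- ld$r
  bad[1, 2] <- 0.5  # break symmetry
  expect_error(ld_matrix(bad, ids), "symmetric")
  bad2 <- ld$r
  diag(bad2)[2] <- 0.99
  expect_error(ld_matrix(bad2, ids), "diagonal")
})

test_that("clumping follows the greedy rule and matches the re-run oracle", {
  # all pairwise r2 = 1: only the smallest p-value survives
  df <- snp_df(3)
  df$pval <- c(1e-10, 1e-9, 1e-8)
  ld1 <- ld_matrix(matrix(1, 3, 3), df$snp_id)
  out <- clump(sumstats(df, "t", "quantitative"), ld1, 0.001, 10000)
  expect_equal(out$snps$snp_id, "rs001")

  # single SNP is identity
  one <- sumstats(snp_df(1), "t", "quantitative")
  expect_equal(clump(one, ld_matrix(matrix(1, 1, 1), "rs001"))$snps,
               one$snps)

  # 50 SNPs, AR(1) rho = 0.9 vs brute-force greedy oracle
  set.seed(77)
  df2 <- snp_df(50)
  df2$pval <- runif(50, 1e-12, 1e-4)
  ld2 <- ar1_ld(df2$snp_id, 0.9)
  got <- clump(sumstats(df2, "t", "quantitative"), ld2, 0.001, 10000)
  expect_equal(sort(got$snps$snp_id),
               clump_oracle(df2, ld2$r, 0.001, 10000))

  # row-order invariance under the deterministic tie-break
  shuffled <- df2[sample.int(50), ]
  got2 <- clump(sumstats(shuffled, "t", "quantitative"), ld2, 0.001, 10000)
  expect_identical(got2$snps$snp_id, got$snps$snp_id)

  # window bounds the search: distant SNP in high LD is retained
  df3 <- snp_df(2, pos = c(1000L, 40000000L))
  df3$pval <- c(1e-10, 1e-8)
  ldh <- ld_matrix(matrix(c(1, 0.99, 0.99, 1), 2), df3$snp_id)
  got3 <- clump(sumstats(df3, "t", "quantitative"), ldh, 0.001,
                window_kb = 10000)
  expect_equal(nrow(got3$snps), 2L)

  # SNP absent from LD reference is a configuration error
  expect_error(clump(sumstats(df2, "t", "quantitative"),
                     ar1_ld(df2$snp_id[-1]), 0.001, 10000), "absent from LD")
})
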