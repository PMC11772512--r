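test_that("druggable-gene lists load, deduplicate and filter by category", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("TNFSF12", "SLC22A4", "SPARC", "KL", "RELT", "ADORA3"), f)
  dl <- load_druggable_list(f)
  expect_length(dl$symbols, 6L)

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("KL", "KL", "kl"), f2)
  expect_length(load_druggable_list(f2)$symbols, 1L)
  expect_true(is_druggable(load_druggable_list(f2), "Kl"))

  # two-column export keeps only druggable-genome rows
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tcategory", "KL\tDruggable Genome",
               "FOO\tclinically actionable", "SPARC\tdruggable genome"), f3)
  expect_setequal(load_druggable_list(f3)$symbols, c("KL", "SPARC"))

  expect_error(druggable_list(character()), "empty")
  expect_error(load_druggable_list(withr::local_tempfile(fileext = ".x")),
               "cannot read")
})

test_that("the bundled druggable-genome fixture exposes the expected symbols", {
  f <- system.file("extdata", "druggable_genome_synthetic.tsv",
                   package = "targetmr")
  dl <- load_druggable_list(f)
  expect_true(all(c("TNFSF12", "SLC22A4", "SPARC", "KL", "RELT", "ADORA3")
                  %in% dl$symbols))
})

test_that("the cascade recovers exactly the planted targets", {
  bench <- simulate_benchmark(seed = 11)
  led <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                     bench$druggable)
  expect_setequal(led$gene_id[led$final],
                  bench$truth$gene_id[bench$truth$planted])
  # ledger is lossless: one row per gene attempted
  expect_equal(nrow(led), nrow(bench$truth))
  # every non-final row names its failing or untestable stage
  expect_true(all(grepl("^(fail|untestable)_", led$status[!led$final])))
  expect_true(all(led$status[led$final] == "pass"))
})

test_that("rerunning with the same seed and config is bit-identical", {
  bench <- simulate_benchmark(n_genes = 6, n_true = 2, n_snps = 80, seed = 4)
  cfg <- cascade_config(seed = 9L)
  led1 <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                      bench$druggable, cfg)
  led2 <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                      bench$druggable, cfg)
  expect_identical(led1, led2)
})

test_that("a gene passing the statistics but absent from the list fails stage 4", {
  bench <- simulate_benchmark(n_genes = 4, n_true = 2, n_snps = 120, seed = 21)
  short_list <- druggable_list(bench$truth$gene_id[1])  # drop the 2nd target
  led <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                     short_list)
  g2 <- led[led$gene_id == bench$truth$gene_id[2], ]
  expect_true(g2$stage3_pass)
  expect_false(g2$stage4_pass)
  expect_equal(g2$status, "fail_stage4_druggable")
  expect_false(g2$final)
})

test_that("tightening a stage threshold never adds final passes", {
  bench <- simulate_benchmark(seed = 11)
  base <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                      bench$druggable)
  tighter <- list(
    cascade_config(smr_p_max = 0.005),
    cascade_config(fdr_alpha = 0.005),
    cascade_config(pph4_min = 0.95, pph34_min = 0.99)
  )
  for (cfg in tighter) {
    led <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                       bench$druggable, cfg)
    expect_true(all(led$gene_id[led$final] %in% base$gene_id[base$final]))
  }
})

test_that("a gene without an LD reference is marked untestable, run continues", {
  bench <- simulate_benchmark(n_genes = 4, n_true = 2, n_snps = 120, seed = 21)
  ld <- bench$ld
  ld[[bench$truth$gene_id[1]]] <- NULL
  led <- run_cascade(bench$eqtl, bench$gwas, ld, bench$annotations,
                     bench$druggable)
  g1 <- led[led$gene_id == bench$truth$gene_id[1], ]
  expect_match(g1$status, "untestable")
  expect_false(g1$final)
  # the other planted gene is unaffected
  expect_true(led$final[led$gene_id == bench$truth$gene_id[2]])
})

test_that("configuration is validated and stamped into the manifest", {
  expect_error(cascade_config(not_a_knob = 1), "unknown option")
  bench <- simulate_benchmark(n_genes = 3, n_true = 1, n_snps = 60, seed = 2)
  led <- run_cascade(bench$eqtl, bench$gwas, bench$ld, bench$annotations,
                     bench$druggable, cascade_config(seed = 42L))
  man <- attr(led, "manifest")
  expect_equal(man$seed, 42L)
  expect_equal(man$package, "targetmr")
  expect_true(nzchar(man$config_digest))
})
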