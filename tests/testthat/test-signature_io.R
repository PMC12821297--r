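test_that("signature table validation enforces the invariants", {
  expect_s3_class(make_table("d1", c("a", "b", "c"), c(1, -1, 0)), "signature_table")
  expect_error(signature_table("d1", c("a", "a"), c(1, 2), c(0.1, 0.2), c(0.1, 0.2)),
               "duplicated gene.*a")
  expect_error(signature_table("d1", "a", Inf, 0.1, 0.1), "non-finite")
  expect_error(signature_table("d1", "a", 1, 1.5, 0.1), "pvalue.*\\[0,1\\]")
  expect_error(signature_table("d1", "a", 1, 0.1, -0.1), "fdr")
})

test_that("TSV round trip is the identity within 1e-9", {
  tab <- withr::with_seed(42, make_table("rt", sprintf("g%04d", 1:2000),
                                         rnorm(2000, sd = 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(tab, path)
  back <- read_signature(path, id = "rt")
  expect_identical(back$gene, tab$gene)
  expect_equal(back$log2fc, tab$log2fc, tolerance = 1e-9)
  expect_equal(back$pvalue, tab$pvalue, tolerance = 1e-9)
  expect_equal(back$fdr, tab$fdr, tolerance = 1e-9)
  expect_identical(dataset_id(back), "rt")
})

test_that("malformed files fail with located diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2fc\tpvalue", "a\t1\t0.5"), path)   # no fdr column
  expect_error(read_signature(path), "missing required column.*fdr")
  writeLines(c("gene\tlog2fc\tpvalue\tfdr", "a\t1\t0.5\t0.5",
               "b\toops\t0.5\t0.5"), path)
  expect_error(read_signature(path), "non-numeric value 'oops'.*row 2")
})

test_that("harmonize maps orthologs with the min-p collapse rule", {
  # two mouse genes -> one human gene; p 0.01 wins over p 0.2
  sig <- signature_table("m1", c("Abc1", "Abc2", "Zzz"), c(0.5, 3, 1),
                         c(0.01, 0.2, 0.5), c(0.02, 0.3, 0.6))
  md <- data.frame(dataset_id = "m1", study_accession = "s", chemical = "THC",
                   species = "mouse", tissue = "brain", platform = "rnaseq",
                   exposure = "in_vivo", stringsAsFactors = FALSE)
  col <- signature_collection(md, list(m1 = sig))
  map <- ortholog_map(c("Abc1", "Abc2"), "mouse", c("ABC", "ABC"))
  out <- suppressWarnings(harmonize(col, map))
  tab <- out$signatures$m1
  expect_identical(tab$gene, "ABC")
  expect_equal(tab$pvalue, 0.01)      # min-p row retained, Zzz dropped
  expect_warning(harmonize(col, map), "dropped 1 unmapped")

  # tie on p -> largest |log2fc| wins
  sig2 <- signature_table("m1", c("A1", "A2"), c(1, -4), c(0.1, 0.1), c(0.1, 0.1))
  col2 <- signature_collection(md, list(m1 = sig2))
  map2 <- ortholog_map(c("A1", "A2"), "mouse", c("HG", "HG"))
  expect_equal(harmonize(col2, map2)$signatures$m1$log2fc, -4)
})

test_that("harmonize passes human data through and is idempotent", {
  col <- noise_collection(20, 3, seed = 5)
  map <- ortholog_map("x", "mouse", "X")
  once <- harmonize(col, map)
  expect_equal(lapply(once$signatures, as.data.frame),
               lapply(col$signatures, as.data.frame))
  expect_identical(harmonize(once, map), once)
})

test_that("harmonize drops everything under an empty map, with a warning", {
  md <- data.frame(dataset_id = "m1", study_accession = "s", chemical = "THC",
                   species = "rat", tissue = "brain", platform = "rnaseq",
                   exposure = "in_vivo", stringsAsFactors = FALSE)
  sig <- make_table("m1", c("r1", "r2"), c(1, -1))
  col <- signature_collection(md, list(m1 = sig))
  empty <- ortholog_map(character(), character(), character())
  expect_warning(out <- harmonize(col, empty), "dropped 2")
  expect_equal(nrow(out$signatures$m1), 0L)
})

test_that("count_significant applies the FDR<5% direction rule", {
  empty <- make_table("e", character(), numeric())
  expect_equal(count_significant(empty), c(n_up = 0L, n_down = 0L))
  tab <- signature_table("d", c("a", "b", "c"), c(1, -1, 2),
                         c(0.001, 0.004, 0.006), c(0.01, 0.04, 0.06))
  expect_equal(count_significant(tab, 0.05), c(n_up = 1L, n_down = 1L))
  # log2fc exactly 0 counted in neither direction
  zero <- signature_table("z", c("a", "b"), c(0, 0.5), c(0.001, 0.001), c(0.01, 0.01))
  expect_equal(count_significant(zero), c(n_up = 1L, n_down = 0L))
})

test_that("count_significant is monotone in the threshold and bounded", {
  tab <- withr::with_seed(3, make_table("m", sprintf("g%d", 1:200), rnorm(200, sd = 2)))
  prev <- c(n_up = 0L, n_down = 0L)
  for (thr in c(0.001, 0.01, 0.05, 0.2, 1)) {
    cur <- count_significant(tab, thr)
    expect_true(all(cur >= prev))
    expect_lte(sum(cur), nrow(tab))
    prev <- cur
  }
})

test_that("collection construction enforces metadata/table agreement", {
  sig <- make_table("d1", "a", 1)
  md <- data.frame(dataset_id = c("d1", "d2"), study_accession = "s",
                   chemical = "THC", species = "human", tissue = "t",
                   platform = "rnaseq", exposure = "in_vivo",
                   stringsAsFactors = FALSE)
  expect_error(signature_collection(md, list(d1 = sig)), "mismatch")
  expect_error(signature_collection(md[1, ], list(d1 = sig, dx = sig)), "mismatch")
  md$platform <- "nanopore"
  expect_error(signature_collection(md[1, ], list(d1 = sig)), "platform")
})

test_that("collection directory round trip preserves tables", {
  col <- noise_collection(30, 4, seed = 9)
  dir <- withr::local_tempdir()
  write_collection(col, dir)
  back <- read_collection(dir)
  expect_identical(names(back$signatures), names(col$signatures))
  expect_equal(back$signatures$d01$log2fc, col$signatures$d01$log2fc,
               tolerance = 1e-9)
  expect_identical(back$metadata$chemical, col$metadata$chemical)
})
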