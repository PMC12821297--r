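test_that("rra_rho matches closed forms on the worked examples", {
  # three top ranks: minimum at j=3 -> r^3
  expect_equal(rra_rho(c(0.01, 0.01, 0.01), 3), 1e-6, tolerance = 1e-15)
  expect_equal(rra_score(c(0.01, 0.01, 0.01), 3), 3e-6, tolerance = 1e-15)
  # single list: Beta(1,1) is uniform -> rho = r
  expect_equal(rra_rho(0.37, 1), 0.37)
  # worst case: all ranks 1 -> rho 1, score capped at 1
  expect_equal(rra_rho(c(1, 1, 1, 1), 4), 1)
  expect_equal(rra_score(c(1, 1, 1, 1), 4), 1)
  expect_error(rra_rho(c(0.5, 0), 2), "\\(0, 1\\]")
  expect_error(rra_rho(c(0.5, 1.2), 2), "\\(0, 1\\]")
  expect_error(rra_rho(rep(0.1, 4), 3), "more ranks than lists")
})

test_that("rra_rho equals binomial-tail enumeration on a grid (n_lists <= 6)", {
  grid <- c(0.01, 0.05, 0.2, 0.5, 0.8, 1.0)
  withr::with_seed(99, {
    for (n in 2:6) {
      for (rep in 1:30) {
        k <- sample(n, 1)
        r <- sort(sample(grid, k, replace = TRUE))
        oracle <- min(vapply(seq_along(r), function(j)
          binom_tail_oracle(j, n, r[j]), 0))
        expect_equal(rra_rho(r, n), oracle, tolerance = 1e-12)
      }
    }
  })
})

test_that("rra_rho is monotone: improving any rank never increases rho", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(3:8, 1)
      r <- sort(runif(sample(n, 1)))
      rho0 <- rra_rho(r, n)
      j <- sample(length(r), 1)
      r2 <- r; r2[j] <- r2[j] * runif(1)
      if (r2[j] <= 0) r2[j] <- r[j] / 2
      expect_lte(rra_rho(r2, n), rho0 + 1e-15)
    }
  })
})

test_that("run_rra flags genes ranked top-decile everywhere and not noise", {
  withr::with_seed(55, {
    m <- matrix(rnorm(200 * 10, sd = 0.2), 200, 10,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("d%02d", 1:10)))
    m["g001", ] <- 3 + rnorm(10, sd = 0.1)    # always near the top
    col <- collection_from_l2fc(m)
    res <- run_rra(col, mode = "per_direction")
    up <- res[res$direction == "up", ]
    expect_true(up$robust[up$gene == "g001"])
    expect_equal(up$gene[1], "g001")          # best score
    # 0.1^10 * 10 Bonferroni bound
    expect_lt(up$score[up$gene == "g001"], 1e-8)
  })
})

test_that("run_rra handles genes missing from some datasets", {
  m <- matrix(rnorm(50 * 4, sd = 0.3), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("d%d", 1:4)))
  m["g01", ] <- 2
  col <- collection_from_l2fc(m)
  sigs <- col$signatures
  t1 <- as.data.frame(sigs$d1)[-1, ]          # drop g01 from d1
  sigs$d1 <- signature_table("d1", t1$gene, t1$log2fc, t1$pvalue, t1$fdr)
  col2 <- signature_collection(col$metadata, sigs)
  res <- run_rra(col2, mode = "per_direction")
  row <- res[res$direction == "up" & res$gene == "g01", ]
  expect_equal(row$n_lists, 3L)               # observed in 3 of 4 lists
  expect_true(row$robust)                     # still called robust
})

test_that("any_direction mode ranks by p-value", {
  genes <- sprintf("g%02d", 1:20)
  tabs <- lapply(1:3, function(i) {
    p <- seq(0.01, 0.96, length.out = 20)
    # g01 most significant everywhere, alternating sign of l2fc
    signature_table(paste0("d", i), genes, rep(c(1, -1), 10) * (1 - p), p,
                    p.adjust(p, "BH"))
  })
  names(tabs) <- paste0("d", 1:3)
  md <- data.frame(dataset_id = names(tabs), study_accession = "s",
                   chemical = "THC", species = "human", tissue = "t",
                   platform = "rnaseq", exposure = "in_vivo",
                   stringsAsFactors = FALSE)
  res <- run_rra(signature_collection(md, tabs), mode = "any_direction")
  expect_equal(res$gene[1], "g01")
  expect_equal(res$rho[1], min(pbeta(1 / 20, 1:3, 3:1)), tolerance = 1e-12)
})

test_that("recurrence applies the >70% direction-consistency rule", {
  # synthesize counts by construction: one gene up in 19 datasets and
  # down in 4; another up 23/down 0; a third up 5/down 5
  n <- 23
  genes <- c("gA", "gB", "gC")
  sigs <- lapply(seq_len(n), function(d) {
    l2 <- c(if (d <= 19) 1 else -1,  1, if (d <= 5) 1 else -1)
    fdr <- c(0.01, 0.01, if (d <= 10) 0.01 else 0.5)
    signature_table(paste0("d", d), genes, l2, fdr, fdr)
  })
  names(sigs) <- paste0("d", seq_len(n))
  md <- data.frame(dataset_id = names(sigs), study_accession = "s",
                   chemical = "CBD", species = "human", tissue = "t",
                   platform = "rnaseq", exposure = "in_vivo",
                   stringsAsFactors = FALSE)
  rec <- recurrence(signature_collection(md, sigs))
  a <- rec[rec$gene == "gA", ]
  expect_equal(c(a$n_up, a$n_down), c(19L, 4L))
  expect_equal(a$consistency, 19 / 23, tolerance = 1e-12)
  expect_true(a$consistent)
  b <- rec[rec$gene == "gB", ]
  expect_equal(c(b$n_up, b$n_down), c(23L, 0L))
  expect_true(b$consistent)
  cc <- rec[rec$gene == "gC", ]
  expect_equal(cc$consistency, 0.5)
  expect_false(cc$consistent)
  # sorted by total descending
  expect_equal(rec$gene, c("gA", "gB", "gC"))
  expect_true(all(rec$consistency >= 0.5 & rec$consistency <= 1))
})

test_that("consistent_call matches the recurrence classifier", {
  expect_true(consistent_call(19, 4))
  expect_true(consistent_call(23, 0))
  expect_false(consistent_call(5, 5))
  expect_false(consistent_call(7, 3))    # exactly 0.70 is not > 0.70
  expect_false(consistent_call(0, 0))
})

test_that("ks_compare: identical samples, full separation, invariance", {
  same <- ks_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  sep <- ks_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$D, 1)
  expect_equal(sep$p, 0.1)               # 2 / choose(6,3)
  expect_identical(sep$method, "exact")
  # invariant under common monotone transform
  a <- c(3, 9, 4, 7); b <- c(5, 1, 12, 8)
  expect_equal(ks_compare(a, b)$D, ks_compare(exp(a), exp(b))$D)
  expect_error(ks_compare(numeric(), 1), "non-empty")
})

test_that("ks_compare asymptotic branch approximates stats::ks.test", {
  withr::with_seed(77, {
    a <- rnorm(30); b <- rnorm(40, mean = 0.8)
    got <- ks_compare(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_identical(got$method, "asymptotic")
    expect_equal(got$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-6)
  })
})
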