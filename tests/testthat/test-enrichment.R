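test_that("hypergeometric tail matches hand-enumerated values", {
  expect_equal(hypergeom_upper_tail(10, 5, 4, 4), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(6, 3, 3, 2), 0.5, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(100, 10, 10, 0), 1)
  expect_error(hypergeom_upper_tail(10, 11, 5, 2), "bounds")
  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "bounds")
  expect_error(hypergeom_upper_tail(10, 5, -1, 0), "non-negative")
})

test_that("tail probabilities match exact enumeration on a random sweep", {
  set.seed(5)
  for (i in 1:300) {
    N <- sample(1:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k),
                 enum_hyper_tail(N, K, n, k), tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand step-up and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  set.seed(6)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone when sorted ascending
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("ORA ranks the matching pathway first and flags coverage", {
  uni <- sprintf("P%02d", 1:60)
  coll <- pathway_collection(
    list(hit = uni[1:10], miss1 = uni[21:30], miss2 = uni[31:45]),
    categories = c(hit = "Immune System/Innate Immune System",
                   miss1 = "Metabolism/Lipids",
                   miss2 = "Metabolism/Lipids"),
    universe = uni)
  res <- run_ora(uni[1:10], coll)
  expect_equal(res$pathway[1], "hit")
  expect_equal(res$k[res$pathway == "hit"], 10)
  expect_true(res$covered[res$pathway == "hit"])
  expect_false("miss1" %in% res$pathway)  # zero overlap is not tested
  # q >= p and covered implies overlap
  expect_true(all(res$q >= res$p - 1e-15))
  expect_true(all(res$k[res$covered] >= 1))
})

test_that("ORA warns on out-of-universe proteins and empty queries", {
  uni <- sprintf("P%02d", 1:20)
  coll <- pathway_collection(list(pw = uni[1:5]), universe = uni)
  expect_warning(res <- run_ora(c(uni[1:3], "XX"), coll), "outside")
  expect_equal(res$n[1], 3)
  expect_warning(expect_warning(res0 <- run_ora("YY", coll), "outside"),
                 "empty")
  expect_equal(nrow(res0), 0)
})

test_that("coverage counts are monotone in alpha", {
  set.seed(7)
  uni <- sprintf("P%03d", 1:300)
  coll <- generate_pathways(40, c(5, 30), uni, "A/B", seed = 7)
  target <- sample(uni, 60)
  covered <- vapply(c(0.01, 0.05, 0.2, 1), function(a) {
    sum(run_ora(target, coll, alpha = a)$covered)
  }, 0)
  expect_true(all(diff(covered) >= 0))
})

test_that("growing the universe recomputes p with unchanged k, K, n", {
  uni <- sprintf("P%02d", 1:30)
  coll <- pathway_collection(list(pw = uni[1:8]), universe = uni)
  target <- uni[1:6]
  r1 <- run_ora(target, coll)
  bigger <- pathway_collection(list(pw = uni[1:8]),
                               universe = c(uni, "Q1", "Q2", "Q3"))
  r2 <- run_ora(target, bigger)
  expect_equal(r2$k, r1$k)
  expect_equal(r2$K, r1$K)
  expect_equal(r2$n, r1$n)
  expect_equal(r2$N, r1$N + 3)
  expect_equal(r2$p, hypergeom_upper_tail(r2$N, r2$K, r2$n, r2$k),
               tolerance = 1e-15)
})

test_that("coverage comparison separates shared and exclusive pathways", {
  res <- data.frame(pathway = c("a", "b"), category = "Immune System/X",
                    k = 1, K = 5, n = 5, N = 50, p = 0.01, q = 0.01,
                    covered = TRUE, stringsAsFactors = FALSE)
  # identical groups: nothing exclusive
  cc <- compare_coverage(list(g1 = res, g2 = res))
  expect_equal(cc$categories[["Immune System/X"]]$shared, c("a", "b"))
  expect_true(all(lengths(cc$categories[["Immune System/X"]]$exclusive)
                  == 0))
  # one empty group
  res0 <- res[0, ]
  cc2 <- compare_coverage(list(g1 = res, g2 = res0))
  expect_equal(cc2$counts["Immune System/X", "g2"], 0L)
  expect_equal(cc2$categories[["Immune System/X"]]$exclusive$g1, c("a", "b"))
  expect_error(compare_coverage(list(g1 = res, g2 = res), "Nope"),
               "available")
})
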