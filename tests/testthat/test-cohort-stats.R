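test_that("percentages recomputed from the published counts match print", {
  cts <- ar_cohort_counts()
  s <- summary_from_counts(cts)
  cell <- function(v, l, g) s$pct[s$variable == v & s$level == l &
                                    s$group == g]
  expect_equal(cell("gender", "female", "users"), 56.4)
  expect_equal(cell("gender", "male", "nonusers"), 52.6)
  expect_equal(cell("atopic_dermatitis", "yes", "users"), 17.8)
  expect_equal(cell("chronic_sinusitis", "yes", "users"), 3.9)
})

test_that("row-level summaries agree with the counts they were built from", {
  cts <- ar_cohort_counts()
  # gender + age + one flag are internally consistent columns
  sub <- cts[cts$variable %in% c("gender", "age_band", "asthma"), ]
  co <- cohort_from_counts(sub)
  s <- summarize_by_group(co, c("gender", "age_band", "asthma"))
  expect_equal(s$count[s$variable == "gender" & s$level == "female" &
                         s$group == "users"], 18900)
  expect_equal(s$pct[s$variable == "gender" & s$level == "female" &
                       s$group == "users"], 56.4)
  expect_equal(s$pct[s$variable == "asthma" & s$group == "nonusers"], 17.7)
  # row-order invariance
  co2 <- co[rev(seq_len(nrow(co))), ]
  expect_equal(summarize_by_group(co2, c("gender", "age_band", "asthma")), s)
})

test_that("exhaustive categorical percentages sum to about 100 per group", {
  co <- generate_cohort(ar_cohort_spec(2000, 3000, seed = 8))
  s <- summarize_by_group(co, c("gender", "age_band", "urbanization",
                                "insured_level", "n_med_types"))
  sums <- stats::aggregate(pct ~ variable + group, data = s, FUN = sum)
  expect_true(all(abs(sums$pct - 100) <= 0.2))
})

test_that("chi-square matches the hand-computed 2x2 value", {
  tab <- matrix(c(10, 20, 20, 10), nrow = 2)
  res <- chisq_table(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
})

test_that("chi-square agrees with an explicit O/E loop on random tables", {
  for (s in 1:25) {
    set.seed(s)
    nr <- sample(2:5, 1)
    tab <- matrix(sample(5:80, nr * 2, replace = TRUE), nrow = nr)
    expect_equal(chisq_table(tab)$statistic, brute_chisq(tab),
                 tolerance = 1e-9)
  }
})

test_that("identical group distributions give chi-square 0 and p 1", {
  co <- data.frame(chm_user = rep(c(TRUE, FALSE), each = 40),
                   g = rep(rep(c("x", "y"), each = 20), 2))
  res <- compare_groups(co, "g")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the published gender split is overwhelmingly significant", {
  tab <- matrix(c(14607, 18900, 29276, 26365), nrow = 2,
                dimnames = list(c("male", "female"), c("u", "n")))
  expect_lt(chisq_table(tab)$p_value, 0.001)
})

test_that("degenerate tables and unknown variables raise errors", {
  expect_error(chisq_table(matrix(c(5, 5), nrow = 2)), "2 groups")
  co <- data.frame(chm_user = c(TRUE, FALSE), g = c("a", "b"))
  expect_error(compare_groups(co, "nope"), "valid names")
  expect_error(summarize_by_group(co, "nope"), "valid names")
})

test_that("pooled and per-group medication-burden shares match print", {
  cts <- ar_cohort_counts()
  expect_equal(pooled_share_counts(cts, "n_med_types", c("2", "3+"),
                                   "all"), 54.4)
  expect_equal(pooled_share_counts(cts, "n_med_types", c("2", "3+"),
                                   "users"), 50.1)
  expect_equal(pooled_share_counts(cts, "n_med_types", c("2", "3+"),
                                   "nonusers"), 57.0)
})

test_that("pooled_share handles predicates and degenerate cases", {
  co <- data.frame(chm_user = rep(TRUE, 10),
                   n_med_types = c(rep("2", 3), rep("0", 7)))
  expect_equal(pooled_share(co, function(d) d$n_med_types == "2"), 30.0)
  expect_equal(pooled_share(co, function(d) rep(TRUE, nrow(d))), 100.0)
  expect_error(pooled_share(co[0, ], function(d) logical(0)), "empty")
})
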