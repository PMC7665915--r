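test_that("support counts transactions containing the whole itemset", {
  px <- tiny_px()
  expect_equal(support(px, "a"), 80)
  expect_equal(support(px, c("a", "b")), 40)
  expect_equal(support(px, c("a", "b", "c")), 20)
  expect_error(support(px[0, ], "a"), "empty")
})

test_that("pair rules on the tiny fixture match hand enumeration", {
  r <- mine_pair_rules(tiny_px(), 0, 0, 0)
  ab <- r[r$antecedent == "a" & r$consequent == "b", ]
  expect_equal(ab$support, 40)
  expect_equal(ab$confidence, 50)
  expect_equal(ab$lift, 0.5 / 0.6, tolerance = 1e-12)
  # b occurs only with a in this fixture -> confidence 100
  px <- data.frame(prescription_id = 1:4, patient_id = "p",
                   herbs = c("a|b", "a|b", "a", "c"))
  r2 <- mine_pair_rules(px, 0, 0, 0)
  expect_equal(r2$confidence[r2$antecedent == "b" & r2$consequent == "a"],
               100)
})

test_that("pairs that never co-occur yield no rule", {
  px <- data.frame(prescription_id = 1:4, patient_id = "p",
                   herbs = c("a", "b", "a", "b"))
  expect_equal(nrow(mine_pair_rules(px, 0.0001, 0, 0)), 0)
})

test_that("miner equals the brute-force ordered-pair scan", {
  for (s in 1:12) {
    px <- random_px(n_txn = 60, n_herbs = 8, seed = s)
    set.seed(s + 1000)
    ms <- runif(1, 0, 5); mc <- runif(1, 0, 30); ml <- runif(1, 0, 1.2)
    got <- mine_pair_rules(px, ms, mc, ml)
    got <- got[order(got$antecedent, got$consequent), ]
    want <- brute_pair_rules(px, ms, mc, ml)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got[c("antecedent", "consequent", "support")],
                     want[c("antecedent", "consequent", "support")])
    expect_equal(got$confidence, want$confidence, tolerance = 1e-12)
    expect_equal(got$lift, want$lift, tolerance = 1e-12)
  }
})

test_that("mined rules satisfy the metric identities and symmetries", {
  px <- random_px(200, 10, seed = 42)
  r <- mine_pair_rules(px, 0, 0, 0)
  # anti-monotonicity: pair support <= each member's support
  singles <- vapply(unique(c(r$antecedent, r$consequent)),
                    function(h) support(px, h), 0)
  expect_true(all(r$support <= singles[r$antecedent] + 1e-12))
  expect_true(all(r$support <= singles[r$consequent] + 1e-12))
  # exact identity lift * support(consequent) = confidence (fractions)
  expect_true(all(abs((r$lift * singles[r$consequent] / 100) -
                        r$confidence / 100) < 1e-12))
  # direction symmetry of support and lift
  key <- paste(pmin(r$antecedent, r$consequent),
               pmax(r$antecedent, r$consequent))
  for (k in unique(key)) {
    d <- r[key == k, ]
    expect_equal(d$support[1], d$support[2])
    expect_equal(d$lift[1], d$lift[2], tolerance = 1e-12)
  }
})

test_that("top_rules collapses directions and applies the stated tie-break", {
  r <- mine_pair_rules(tiny_px(), 0, 0, 0)
  top <- top_rules(r, 10)
  key <- paste(pmin(top$antecedent, top$consequent),
               pmax(top$antecedent, top$consequent))
  expect_false(any(duplicated(key)))
  # ties on support and confidence resolve to the smaller pair name first
  expect_equal(key[1], "a b")
  expect_equal(nrow(top_rules(r, 2)), 2)
  expect_equal(nrow(top_rules(r, 1000)), length(unique(key)))
  # the representative direction is the higher-confidence one
  ab <- r[r$antecedent %in% c("a", "b") & r$consequent %in% c("a", "b"), ]
  expect_equal(top$confidence[1], max(ab$confidence))
})

test_that("prevalence ranking finds the planted top herb and type ranks", {
  px <- generate_prescriptions(
    ar_network_spec(n_prescriptions = 10000, seed = 13))
  prev <- prevalence_ranking(px, ar_herb_types())
  expect_equal(prev$herb[1], "Xin-Yi-Qing-Fei-Tang")
  expect_lt(abs(prev$prevalence[1] - 25.5),
            3 * sqrt(0.255 * 0.745 / 10000) * 100)
  # planted 19.1-style check: core of cluster 3 at its cluster weight
  ang <- prev[prev$herb == "Angelica dahurica", ]
  expect_lt(abs(ang$prevalence - 16.2),
            3 * sqrt(0.162 * 0.838 / 10000) * 100)
  # rank is within type
  expect_equal(prev$rank[prev$type == "HF"][1], 1)
  expect_equal(prev$rank[prev$type == "SH"][1], 1)
})

test_that("unmapped codes are labeled unknown with a warning; ties sort by name", {
  px <- data.frame(prescription_id = 1:2, patient_id = "p",
                   herbs = c("b|a", "a|b"))
  expect_warning(prev <- prevalence_ranking(
    px, data.frame(herb = "a", type = "SH")), "unknown")
  expect_equal(prev$herb, c("a", "b"))  # equal support, lexicographic
  expect_equal(prev$type[prev$herb == "b"], "unknown")
})

test_that("mean dose per herb averages over its prescriptions", {
  px <- data.frame(prescription_id = 1:2, patient_id = "p",
                   herbs = c("a|b", "a"), dose = c("4|2", "6"))
  prev <- prevalence_ranking(px)
  expect_equal(prev$mean_dose[prev$herb == "a"], 5)
  expect_equal(prev$mean_dose[prev$herb == "b"], 2)
})

test_that("mean prescription size equals the arithmetic mean of sizes", {
  px <- tiny_px()
  expect_equal(mean_prescription_size(px), mean(c(2, 3, 2, 2, 1)))
})

test_that("frequent itemsets obey apriori anti-monotonicity", {
  px <- random_px(100, 7, seed = 3)
  fi <- frequent_itemsets(px, min_support = 5, max_k = 3)
  if (nrow(fi)) {
    for (i in seq_len(nrow(fi))) {
      items <- strsplit(fi$items[i], "|", fixed = TRUE)[[1]]
      expect_equal(fi$support[i], support(px, items))
      for (j in seq_along(items)) {
        expect_gte(support(px, items[-j]), fi$support[i])
      }
    }
  }
})
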