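test_that("cohort generation is deterministic and matches group sizes", {
  spec <- ar_cohort_spec(n_users = 500, n_nonusers = 800, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 1300)
  expect_equal(sum(a$chm_user), 500)
  expect_true(all(a$age_band %in% c("0-20", "21-40", "41+")))
})

test_that("degenerate category probabilities are honoured exactly", {
  probs <- list(gender = list(
    users = c(female = 1, male = 0), nonusers = c(female = 1, male = 0)))
  co <- generate_cohort(cohort_spec(50, 50, probs, seed = 2))
  expect_true(all(co$gender == "female"))
})

test_that("observed category shares stay within binomial bounds", {
  probs <- list(gender = list(
    users = c(female = 0.564, male = 0.436),
    nonusers = c(female = 0.474, male = 0.526)))
  co <- generate_cohort(cohort_spec(10000, 10000, probs, seed = 1))
  p_hat <- mean(co$gender[co$chm_user] == "female")
  sd3 <- 3 * sqrt(0.564 * (1 - 0.564) / 10000)
  expect_lt(abs(p_hat - 0.564), sd3)
})

test_that("invalid probability vectors are rejected with the variable name", {
  probs <- list(gender = list(users = c(f = 0.6, m = 0.5),
                              nonusers = c(f = 0.5, m = 0.5)))
  expect_error(cohort_spec(10, 10, probs), "gender")
})

test_that("generated cohort frequencies pass a chi-square GOF sweep", {
  # 20 seeds, n = 10,000; at most one rejection at alpha = 0.001
  p_users <- c(a = 0.375, b = 0.309, c = 0.316)
  probs <- list(age = list(users = p_users,
                           nonusers = c(a = 0.412, b = 0.231, c = 0.357)))
  fails <- 0L
  for (s in 1:20) {
    co <- generate_cohort(cohort_spec(10000, 0, probs, seed = s))
    obs <- table(factor(co$age, levels = names(p_users)))
    p <- suppressWarnings(
      stats::chisq.test(obs, p = p_users)$p.value)
    if (p < 0.001) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("transactions never repeat a herb and honour a degenerate size", {
  spec <- planted_network_spec(
    clusters = list(list(herbs = c("a", "b", "c", "d", "e", "f"),
                         core = "a")),
    background_herbs = sprintf("z%d", 1:10),
    size_dist = c(`5` = 1), n_prescriptions = 1000, seed = 3)
  px <- generate_prescriptions(spec)
  items <- strsplit(px$herbs, "|", fixed = TRUE)
  expect_true(all(lengths(items) == 5))
  expect_true(all(vapply(items, anyDuplicated, 0L) == 0))
})

test_that("empirical mean transaction size tracks the configured mean", {
  px <- generate_prescriptions(
    ar_network_spec(n_prescriptions = 50000, seed = 7))
  expect_lt(abs(mean_prescription_size(px) - 5.6), 0.1)
})

test_that("pure within-cluster transactions stay inside one cluster", {
  spec <- planted_network_spec(
    clusters = list(
      list(herbs = c("a1", "a2", "a3", "a4", "a5"), core = "a1",
           co_draw = 1),
      list(herbs = c("b1", "b2", "b3", "b4", "b5"), core = "b1",
           co_draw = 1)),
    size_dist = stats::setNames(c(.5, .5), c(3, 4)),
    n_prescriptions = 500, background_mass = 0, seed = 5)
  px <- generate_prescriptions(spec)
  items <- strsplit(px$herbs, "|", fixed = TRUE)
  cl <- list(paste0("a", 1:5), paste0("b", 1:5))
  ok <- vapply(seq_along(items), function(i) {
    all(items[[i]] %in% cl[[px$truth_cluster[i]]])
  }, TRUE)
  expect_true(all(ok))
})

test_that("oversized transactions relative to the herb pool are rejected", {
  expect_error(planted_network_spec(
    clusters = list(list(herbs = c("a", "b"), core = "a")),
    size_dist = c(`9` = 1), n_prescriptions = 10),
    "distinct herbs")
})

test_that("prescription generation is reproducible under a fixed seed", {
  spec <- toy_planted_spec(seed = 9, n = 300)
  expect_identical(generate_prescriptions(spec),
                   generate_prescriptions(spec))
})

test_that("ingredient tables have the configured scale and valid scores", {
  herbs <- sprintf("H%02d", 1:31)
  spec <- ingredient_db_spec(herbs, ingredients_per_herb = c(78, 79),
                             proteins = sprintf("P%03d", 1:50), seed = 4)
  db <- generate_ingredient_db(spec)
  expect_true(abs(nrow(db$ingredients) - 2432) < 40)
  expect_true(all(db$ingredients$ob >= 0 & db$ingredients$ob <= 1))
  expect_true(all(db$ingredients$dl >= 0 & db$ingredients$dl <= 1))
  # every ingredient belongs to exactly one herb record
  expect_false(anyDuplicated(db$ingredients$ingredient) > 0)
  expect_true(all(db$targets$agent %in% db$ingredients$ingredient))
  expect_identical(db, generate_ingredient_db(spec))
})

test_that("ingredient generation rejects an empty protein universe", {
  expect_error(ingredient_db_spec(herbs = "H1", proteins = character()),
               "universe")
})

test_that("pathway generation respects the universe and determinism", {
  uni <- sprintf("P%03d", 1:100)
  coll <- generate_pathways(140, c(5, 20), uni, c("A/B", "C/D"), seed = 6)
  expect_length(coll$pathways, 140)
  expect_true(all(unlist(coll$pathways) %in% uni))
  expect_true(all(coll$categories %in% c("A/B", "C/D")))
  coll2 <- generate_pathways(140, c(5, 20), uni, c("A/B", "C/D"), seed = 6)
  expect_identical(coll, coll2)
  # degenerate size: every pathway equals the universe
  full <- generate_pathways(3, c(100, 100), uni, "A/B", seed = 1)
  expect_true(all(vapply(full$pathways, function(m) setequal(m, uni), TRUE)))
  expect_error(generate_pathways(3, c(101, 101), uni, "A/B", seed = 1),
               "size_range")
})
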