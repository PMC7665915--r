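# Independent brute-force oracles and small fixture builders.

# Tiny five-transaction fixture used throughout: {ab, abc, ac, bc, a}.
tiny_px <- function() {
  data.frame(prescription_id = sprintf("RX%d", 1:5),
             patient_id = "p",
             herbs = c("a|b", "a|b|c", "a|c", "b|c", "a"),
             stringsAsFactors = FALSE)
}

# Random transactions over `n_herbs` single-letter-ish codes.
random_px <- function(n_txn, n_herbs, seed) {
  set.seed(seed)
  herbs <- sprintf("h%02d", seq_len(n_herbs))
  rows <- vapply(seq_len(n_txn), function(i) {
    k <- sample.int(min(n_herbs, 6), 1)
    paste(sort(sample(herbs, k)), collapse = "|")
  }, "")
  data.frame(prescription_id = sprintf("RX%04d", seq_len(n_txn)),
             patient_id = "p", herbs = rows, stringsAsFactors = FALSE)
}

# Brute-force itemset support by transaction enumeration.
brute_support <- function(px, itemset) {
  items <- strsplit(px$herbs, "|", fixed = TRUE)
  100 * sum(vapply(items, function(x) all(itemset %in% x), TRUE)) /
    length(items)
}

# Brute-force double loop over all ordered herb pairs.
brute_pair_rules <- function(px, min_support = 0, min_confidence = 0,
                             min_lift = 0) {
  items <- lapply(strsplit(px$herbs, "|", fixed = TRUE), unique)
  herbs <- sort(unique(unlist(items)))
  n <- length(items)
  out <- list()
  for (a in herbs) {
    for (b in herbs) {
      if (a == b) next
      n_ab <- sum(vapply(items, function(x) a %in% x && b %in% x, TRUE))
      if (n_ab == 0) next
      n_a <- sum(vapply(items, function(x) a %in% x, TRUE))
      n_b <- sum(vapply(items, function(x) b %in% x, TRUE))
      supp <- 100 * n_ab / n
      conf <- 100 * n_ab / n_a
      lift <- (conf / 100) / ((100 * n_b / n) / 100)
      if (supp >= min_support && conf >= min_confidence &&
          lift >= min_lift) {
        out[[length(out) + 1L]] <- data.frame(
          antecedent = a, consequent = b, support = supp,
          confidence = conf, lift = lift, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), stringsAsFactors = FALSE))
  }
  r <- do.call(rbind, out)
  r[order(r$antecedent, r$consequent), ]
}

# Explicit O/E-loop Pearson chi-square.
brute_chisq <- function(tab) {
  tab <- as.matrix(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

# Exact hypergeometric upper tail by summing log-binomial terms.
enum_hyper_tail <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Step-up BH by hand.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Small deterministic planted spec (two clusters + one dyad).
toy_planted_spec <- function(seed = 1, n = 2000, co_draw = 0.9,
                             background_mass = 0.02) {
  planted_network_spec(
    clusters = list(
      list(herbs = c("A1", "A2", "A3", "A4"), core = "A1",
           co_draw = co_draw),
      list(herbs = c("B1", "B2", "B3"), core = "B1", co_draw = co_draw),
      list(herbs = c("C1", "C2"), core = "C1", co_draw = co_draw)),
    background_herbs = sprintf("Z%02d", 1:20),
    size_dist = stats::setNames(c(.4, .6), c(2, 3)),
    n_prescriptions = n,
    cluster_weights = c(.45, .35, .2),
    background_mass = background_mass,
    seed = seed)
}

# The 20-seed recovery run is shared between the clustering- and
# core-recovery checks; cache it for the duration of the test run.
.recovery_cache <- new.env(parent = emptyenv())
cached_planted_recovery <- function() {
  if (is.null(.recovery_cache$rec)) {
    .recovery_cache$rec <- planted_recovery(1:20)
  }
  .recovery_cache$rec
}
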