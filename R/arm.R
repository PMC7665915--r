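# Association-rule mining over prescription transactions.
#
# Transactions are rows of a prescription table with a pipe-delimited
# `herbs` field; duplicate codes within one prescription are collapsed to
# set semantics before any counting. Support is prescription-level: the
# denominator is always the number of prescriptions, not patients.

# Logical incidence matrix (transactions x herbs), set semantics.
incidence_matrix <- function(prescriptions) {
  items <- herb_list(prescriptions)
  items <- lapply(items, unique)
  herbs <- sort(unique(unlist(items)))
  m <- matrix(FALSE, nrow = length(items), ncol = length(herbs),
              dimnames = list(NULL, herbs))
  ij <- cbind(rep(seq_along(items), lengths(items)),
              match(unlist(items), herbs))
  m[ij] <- TRUE
  m
}

#' Support of an itemset
#'
#' Percentage of prescriptions containing every item of the set.
#'
#' @param prescriptions prescription table (see [generate_prescriptions()]
#'   for the layout).
#' @param itemset nonempty character vector of herb codes.
#' @return percent on `[0, 100]`.
#' @export
support <- function(prescriptions, itemset) {
  if (nrow(prescriptions) == 0L) stop("empty prescription table",
                                      call. = FALSE)
  stopifnot(length(itemset) >= 1L)
  items <- herb_list(prescriptions)
  hit <- vapply(items, function(x) all(itemset %in% x), TRUE)
  100 * sum(hit) / length(items)
}

#' Mine pairwise association rules
#'
#' Counts all herb pairs exactly (no sampling) and emits both directions
#' A -> B and B -> A for every unordered pair whose joint support passes
#' `min_support`; each direction is retained only if its confidence and
#' lift pass their thresholds.
#'
#' Metrics follow the standard definitions: support is the percentage of
#' prescriptions containing both herbs, confidence the percentage of the
#' antecedent's prescriptions that also contain the consequent, and lift
#' the ratio of confidence to the consequent's marginal support (both as
#' fractions), so `lift * support(consequent) = confidence` holds exactly.
#'
#' @param prescriptions prescription table.
#' @param min_support minimum pair support, percent (default 1.0).
#' @param min_confidence minimum confidence, percent (default 15).
#' @param min_lift minimum lift (default 1.0).
#' @return data.frame with `antecedent`, `consequent`, `support`,
#'   `confidence`, `lift`, sorted by support then confidence descending.
#' @export
mine_pair_rules <- function(prescriptions, min_support = 1,
                            min_confidence = 15, min_lift = 1) {
  if (nrow(prescriptions) == 0L) stop("empty prescription table",
                                      call. = FALSE)
  stopifnot(min_support >= 0, min_confidence >= 0, min_lift >= 0)
  m <- incidence_matrix(prescriptions)
  n <- nrow(m)
  cnt <- crossprod(m * 1)                     # pair co-occurrence counts
  singles <- diag(cnt)
  herbs <- colnames(m)
  ut <- which(upper.tri(cnt) & cnt > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support = numeric(), confidence = numeric(),
                      lift = numeric(), stringsAsFactors = FALSE))
  }
  pair_n <- cnt[ut]
  supp <- 100 * pair_n / n
  keep <- supp >= min_support
  ut <- ut[keep, , drop = FALSE]
  pair_n <- pair_n[keep]
  supp <- supp[keep]
  a <- herbs[ut[, 1]]; b <- herbs[ut[, 2]]
  rules <- data.frame(
    antecedent = c(a, b), consequent = c(b, a),
    support = c(supp, supp),
    confidence = 100 * c(pair_n / singles[ut[, 1]],
                         pair_n / singles[ut[, 2]]),
    stringsAsFactors = FALSE
  )
  cons_supp <- 100 * singles[rules$consequent] / n
  rules$lift <- (rules$confidence / 100) / (cons_supp / 100)
  rules <- rules[rules$confidence >= min_confidence &
                   rules$lift >= min_lift, , drop = FALSE]
  rules <- rules[order(-rules$support, -rules$confidence,
                       rules$antecedent, rules$consequent), ]
  rownames(rules) <- NULL
  rules
}

#' Select the top rules
#'
#' Ranks rules by pair support descending, breaking ties by confidence
#' descending and then by the lexicographic pair name. With
#' `collapse_direction` each unordered pair appears once, represented by
#' its higher-confidence direction (ties resolved toward the
#' lexicographically smaller antecedent).
#'
#' @param rules data.frame from [mine_pair_rules()].
#' @param n number of rules to keep (at least 1).
#' @param collapse_direction collapse A->B / B->A to one row (default
#'   `TRUE`).
#' @return data.frame of at most `n` rules.
#' @export
top_rules <- function(rules, n = 100, collapse_direction = TRUE) {
  stopifnot(n >= 1)
  if (nrow(rules) == 0L) return(rules)
  pair <- paste(pmin(rules$antecedent, rules$consequent),
                pmax(rules$antecedent, rules$consequent), sep = " | ")
  if (collapse_direction) {
    ord <- order(pair, -rules$confidence, rules$antecedent)
    r <- rules[ord, ]
    r <- r[!duplicated(pair[ord]), ]
    pair <- pair[ord][!duplicated(pair[ord])]
  } else {
    r <- rules
  }
  ord <- order(-r$support, -r$confidence, pair)
  r <- r[ord, ]
  rownames(r) <- NULL
  head(r, n)
}

#' Prevalence ranking of single herbs
#'
#' Per-herb support across all prescriptions, mean daily dose when a dose
#' field is present, and the rank within herb type (herbal formula vs
#' single herb). Ties in support are resolved lexicographically.
#'
#' @param prescriptions prescription table; an optional `dose` column holds
#'   pipe-delimited grams/day aligned with the `herbs` field.
#' @param herb_type_map optional data.frame with columns `herb`, `type`;
#'   codes missing from the map are labeled `"unknown"` with a warning.
#' @return data.frame with `herb`, `type`, `prevalence` (percent),
#'   `mean_dose` (NA without dose data), `rank` (within type).
#' @export
prevalence_ranking <- function(prescriptions, herb_type_map = NULL) {
  if (nrow(prescriptions) == 0L) stop("empty prescription table",
                                      call. = FALSE)
  m <- incidence_matrix(prescriptions)
  herbs <- colnames(m)
  prev <- 100 * colSums(m) / nrow(m)
  mean_dose <- rep(NA_real_, length(herbs))
  if (!is.null(prescriptions$dose)) {
    items <- herb_list(prescriptions)
    doses <- lapply(strsplit(prescriptions$dose, "|", fixed = TRUE),
                    as.numeric)
    all_h <- unlist(items)
    all_d <- unlist(doses)
    sums <- tapply(all_d, all_h, sum)
    cnts <- tapply(all_d, all_h, length)
    mean_dose <- as.numeric(sums[herbs] / cnts[herbs])
  }
  type <- rep("unknown", length(herbs))
  if (!is.null(herb_type_map)) {
    idx <- match(herbs, herb_type_map$herb)
    type <- as.character(herb_type_map$type[idx])
    if (anyNA(idx)) {
      warning("herb code(s) missing from type map, labeled 'unknown': ",
              paste(herbs[is.na(idx)], collapse = ", "))
      type[is.na(idx)] <- "unknown"
    }
  }
  out <- data.frame(herb = herbs, type = type, prevalence = prev,
                    mean_dose = mean_dose, stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$herb), ]
  out$rank <- stats::ave(seq_len(nrow(out)), out$type,
                         FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Mean number of herbs per prescription
#'
#' @param prescriptions prescription table.
#' @return arithmetic mean of transaction sizes (set semantics).
#' @export
mean_prescription_size <- function(prescriptions) {
  mean(lengths(lapply(herb_list(prescriptions), unique)))
}

#' Frequent itemsets of size up to `max_k`
#'
#' Level-wise apriori search using the anti-monotonicity of support:
#' a `(k+1)`-itemset is only counted if all its `k`-subsets are frequent.
#' Exploratory extension beyond the pairwise rules the network is built
#' from.
#'
#' @param prescriptions prescription table.
#' @param min_support minimum support, percent.
#' @param max_k largest itemset size (2 to 4).
#' @return data.frame with `items` (pipe-delimited, sorted), `size`,
#'   `support`.
#' @export
frequent_itemsets <- function(prescriptions, min_support = 1, max_k = 2) {
  stopifnot(max_k >= 2, max_k <= 4)
  m <- incidence_matrix(prescriptions)
  n <- nrow(m)
  herbs <- colnames(m)
  freq1 <- herbs[100 * colSums(m) / n >= min_support]
  out <- list()
  level <- lapply(freq1, identity)
  k <- 1L
  while (k < max_k && length(level) > 0L) {
    cand <- list()
    keys <- vapply(level, paste, "", collapse = "|")
    for (i in seq_along(level)) {
      base <- level[[i]]
      for (h in freq1[freq1 > base[length(base)]]) {
        cs <- c(base, h)
        subs_ok <- all(vapply(seq_along(cs), function(j) {
          paste(cs[-j], collapse = "|") %in% keys || k == 1L
        }, TRUE))
        if (subs_ok) cand[[length(cand) + 1L]] <- cs
      }
    }
    level <- list()
    for (cs in cand) {
      s <- 100 * sum(rowSums(m[, cs, drop = FALSE]) == length(cs)) / n
      if (s >= min_support) {
        level[[length(level) + 1L]] <- cs
        out[[length(out) + 1L]] <- data.frame(
          items = paste(cs, collapse = "|"), size = length(cs),
          support = s, stringsAsFactors = FALSE)
      }
    }
    k <- k + 1L
  }
  if (length(out) == 0L) {
    return(data.frame(items = character(), size = integer(),
                      support = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-res$support, res$items), , drop = FALSE]
}
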