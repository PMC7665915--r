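# Hypergeometric overrepresentation analysis against a pathway collection.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of annotated proteins `X` drawn when `n`
#' proteins are sampled without replacement from a universe of `N`
#' proteins of which `K` belong to the pathway. Computed with the exact
#' log-space hypergeometric tail, numerically stable for universes up to
#' at least 1e5.
#'
#' @param N universe size.
#' @param K pathway size within the universe.
#' @param n query set size.
#' @param k observed overlap.
#' @return probability in `(0, 1]`; `k = 0` gives exactly 1. All four
#'   arguments are vectorized (recycled to a common length).
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  args <- cbind(N = N, K = K, n = n, k = k)  # recycles
  if (anyNA(args) || any(args < 0) || any(args != trunc(args))) {
    stop("hypergeometric arguments must be non-negative integers",
         call. = FALSE)
  }
  N <- args[, "N"]; K <- args[, "K"]; n <- args[, "n"]; k <- args[, "k"]
  if (any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    stop("invalid hypergeometric bounds: need K <= N, n <= N, ",
         "k <= min(n, K)", call. = FALSE)
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  unname(p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment with cumulative-minimum enforcement;
#' the input order is preserved in the output.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(is.numeric(p_values), all(p_values >= 0 & p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Overrepresentation analysis of a protein set
#'
#' Tests every pathway with at least one protein in common with the query
#' set. The universe defaults to all proteins annotated in the collection;
#' query proteins outside the universe are dropped with a warning.
#' A pathway counts as covered when its adjusted p-value is at or below
#' `alpha` (set `criterion = "p"` for a raw-p sensitivity mode).
#'
#' @param target_set character protein set.
#' @param collection a `pathway_collection`.
#' @param alpha coverage significance level (default 0.05).
#' @param criterion `"q"` (BH-adjusted, default) or `"p"` (raw).
#' @param method multiplicity adjustment, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return data.frame with one row per tested pathway: `pathway`,
#'   `category`, `k` (overlap), `K` (pathway size), `n` (effective query
#'   size), `N` (universe size), `p`, `q`, logical `covered`; sorted by
#'   `p`. Empty effective query gives an empty result with a warning.
#' @export
run_ora <- function(target_set, collection, alpha = 0.05,
                    criterion = c("q", "p"), method = c("BH", "bonferroni")) {
  stopifnot(inherits(collection, "pathway_collection"))
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  uni <- collection$universe
  eff <- unique(target_set)
  outside <- setdiff(eff, uni)
  if (length(outside)) {
    warning(length(outside), " query protein(s) outside the universe ",
            "were dropped")
    eff <- intersect(eff, uni)
  }
  empty <- data.frame(pathway = character(), category = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      covered = logical(), stringsAsFactors = FALSE)
  if (length(eff) == 0L) {
    warning("empty effective target set")
    return(empty)
  }
  N <- length(uni)
  n <- length(eff)
  k <- vapply(collection$pathways, function(m) length(intersect(m, eff)), 0L)
  K <- lengths(collection$pathways)
  keep <- k >= 1L
  if (!any(keep)) return(empty)
  p <- mapply(function(Ki, ki) hypergeom_upper_tail(N, Ki, n, ki),
              K[keep], k[keep])
  q <- if (method == "BH") bh_fdr(p) else pmin(1, p * length(p))
  out <- data.frame(pathway = names(collection$pathways)[keep],
                    category = unname(collection$categories[keep]),
                    k = unname(k[keep]), K = unname(K[keep]),
                    n = n, N = N, p = unname(p), q = unname(q),
                    covered = (if (criterion == "q") q else p) <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  out
}

# First `depth` levels of a category path ("A/B/C" -> "A/B").
category_rollup <- function(path, depth = 2) {
  vapply(strsplit(path, "/", fixed = TRUE), function(x) {
    paste(head(x, depth), collapse = "/")
  }, "")
}

#' Compare pathway coverage between agent groups
#'
#' For every category (rolled up to the first two levels of the category
#' path) under the given top-level filter, lists the pathways covered by
#' each group, the shared ones, and those exclusive to a single group
#' (the complementarity pattern).
#'
#' @param results_by_group named list (at least two entries) of
#'   [run_ora()] result data.frames.
#' @param category_filter top-level category to restrict to (default
#'   `"Immune System"`); use `NULL` for all categories.
#' @return list with `categories` (per rolled-up category: `covered`
#'   per-group sets, `shared`, `exclusive` per group) and `counts`
#'   (category x group matrix of covered-pathway counts).
#' @export
compare_coverage <- function(results_by_group,
                             category_filter = "Immune System") {
  stopifnot(is.list(results_by_group), length(results_by_group) >= 2L,
            !is.null(names(results_by_group)))
  covered <- lapply(results_by_group, function(r) r[r$covered, , drop = FALSE])
  all_cats <- unique(unlist(lapply(covered, function(r) r$category)))
  tops <- unique(vapply(strsplit(all_cats, "/", fixed = TRUE), `[[`, "", 1))
  if (!is.null(category_filter)) {
    if (!category_filter %in% tops) {
      stop("unknown category filter '", category_filter,
           "'; available: ", paste(sort(tops), collapse = ", "),
           call. = FALSE)
    }
    covered <- lapply(covered, function(r) {
      r[startsWith(r$category, category_filter), , drop = FALSE]
    })
  }
  cats <- sort(unique(category_rollup(
    unlist(lapply(covered, function(r) r$category)))))
  groups <- names(results_by_group)
  per_cat <- lapply(cats, function(cc) {
    sets <- lapply(covered, function(r) {
      sort(r$pathway[category_rollup(r$category) == cc])
    })
    shared <- Reduce(intersect, sets)
    exclusive <- lapply(seq_along(sets), function(i) {
      setdiff(sets[[i]], unlist(sets[-i]))
    })
    names(exclusive) <- groups
    list(covered = sets, shared = shared, exclusive = exclusive)
  })
  names(per_cat) <- cats
  counts <- matrix(0L, nrow = length(cats), ncol = length(groups),
                   dimnames = list(cats, groups))
  for (cc in cats) {
    counts[cc, ] <- vapply(per_cat[[cc]]$covered, length, 0L)
  }
  list(categories = per_cat, counts = counts)
}
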