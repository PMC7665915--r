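#' Grouped counts and percentages for a user/nonuser cohort
#'
#' Produces the classic baseline-characteristics comparison: per variable
#' and level, the count and percentage within each group. Percentages use
#' the group size as denominator; for logical flag variables a single row
#' reports the share of rows with the flag set.
#'
#' @param cohort cohort data.frame with a logical grouping column.
#' @param variables character vector of columns to summarise.
#' @param group name of the logical grouping column (default `"chm_user"`).
#' @return data.frame with columns `variable`, `level`, `group`
#'   (`"users"`/`"nonusers"`), `count` and `pct` (half-up rounded to one
#'   decimal).
#' @export
summarize_by_group <- function(cohort, variables, group = "chm_user") {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0L)
  bad <- setdiff(c(variables, group), names(cohort))
  if (length(bad)) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(names(cohort), collapse = ", "),
         call. = FALSE)
  }
  g <- cohort[[group]]
  stopifnot(is.logical(g))
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    for (grp in c("users", "nonusers")) {
      idx <- if (grp == "users") g else !g
      n_grp <- sum(idx)
      if (is.logical(x)) {
        cnt <- sum(x[idx])
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = "yes", group = grp, count = cnt,
          pct = round_half_up(100 * cnt / n_grp, 1),
          stringsAsFactors = FALSE)
      } else {
        lev <- sort(unique(as.character(x)))
        cnt <- vapply(lev, function(l) sum(x[idx] == l), 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, group = grp, count = as.integer(cnt),
          pct = round_half_up(100 * cnt / n_grp, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-square comparison of a variable between groups
#'
#' Pearson chi-square test of independence on the level-by-group
#' contingency table, without continuity correction by default (an option
#' exposes the corrected variant for 2x2 tables).
#'
#' @param cohort cohort data.frame.
#' @param variable column to test.
#' @param group logical grouping column name.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `df`, `p_value` and the observed `table`.
#' @export
compare_groups <- function(cohort, variable, group = "chm_user",
                           correct = FALSE) {
  stopifnot(is.data.frame(cohort))
  bad <- setdiff(c(variable, group), names(cohort))
  if (length(bad)) {
    stop("unknown variable(s): ", paste(bad, collapse = ", "),
         "; valid names are: ", paste(names(cohort), collapse = ", "),
         call. = FALSE)
  }
  tab <- table(as.character(cohort[[variable]]), cohort[[group]])
  chisq_table(tab, correct = correct)
}

#' Chi-square test on a prebuilt contingency table
#'
#' @param tab matrix or table of observed counts (levels x groups).
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `df`, `p_value`, `expected`, `table`.
#' @export
chisq_table <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 levels and 2 groups with nonzero totals",
         call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("degenerate contingency table: zero expected cell", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = expected, table = tab)
}

#' Share of the cohort satisfying a predicate
#'
#' @param cohort cohort data.frame.
#' @param predicate function taking the data.frame and returning a logical
#'   vector (one value per row, no `NA`).
#' @return percentage, half-up rounded to one decimal.
#' @export
pooled_share <- function(cohort, predicate) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  keep <- predicate(cohort)
  if (!is.logical(keep) || length(keep) != nrow(cohort) || anyNA(keep)) {
    stop("predicate must return one non-NA logical per row", call. = FALSE)
  }
  round_half_up(100 * sum(keep) / nrow(cohort), 1)
}

#' Grouped percentages recomputed from a published count table
#'
#' Computes the per-level percentages directly from printed counts, with
#' the group sizes (taken from the first exhaustive categorical, usually
#' gender) as denominators — the arithmetic behind a published baseline
#' table. Count columns of a printed table may be off by a rounding unit
#' against the group size, which is why the denominator is the group
#' size, not the column sum.
#'
#' @param counts data.frame with `variable`, `level`, `users`,
#'   `nonusers` (flag variables carry one `"yes"` row).
#' @return long data.frame like [summarize_by_group()]: `variable`,
#'   `level`, `group`, `count`, `pct`.
#' @export
summary_from_counts <- function(counts) {
  stopifnot(all(c("variable", "level", "users", "nonusers") %in%
                  names(counts)))
  first <- counts[counts$variable == counts$variable[1], ]
  if (nrow(first) < 2L) {
    stop("the first variable must be an exhaustive categorical",
         call. = FALSE)
  }
  sizes <- c(users = sum(first$users), nonusers = sum(first$nonusers))
  out <- do.call(rbind, lapply(c("users", "nonusers"), function(g) {
    data.frame(variable = counts$variable, level = counts$level,
               group = g, count = counts[[g]],
               pct = round_half_up(100 * counts[[g]] / sizes[[g]], 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pooled or per-group share from a published count table
#'
#' @param counts data.frame as in [summary_from_counts()].
#' @param variable the variable to select levels from.
#' @param levels level(s) forming the numerator.
#' @param group `"all"` (both groups pooled), `"users"` or `"nonusers"`.
#' @return percentage, half-up rounded to one decimal.
#' @export
pooled_share_counts <- function(counts, variable, levels,
                                group = c("all", "users", "nonusers")) {
  group <- match.arg(group)
  first <- counts[counts$variable == counts$variable[1], ]
  sizes <- c(users = sum(first$users), nonusers = sum(first$nonusers))
  d <- counts[counts$variable == variable & counts$level %in% levels, ]
  if (nrow(d) == 0L) stop("no matching rows for '", variable, "'",
                          call. = FALSE)
  num <- switch(group, all = sum(d$users) + sum(d$nonusers),
                users = sum(d$users), nonusers = sum(d$nonusers))
  den <- switch(group, all = sum(sizes), users = sizes[["users"]],
                nonusers = sizes[["nonusers"]])
  round_half_up(100 * num / den, 1)
}

#' Wide, table-one style layout of a grouped summary
#'
#' Reshapes [summarize_by_group()] output to one row per (variable, level)
#' with user and nonuser counts and percentages side by side, and attaches
#' the per-variable chi-square p-value.
#'
#' @param cohort cohort data.frame.
#' @param variables columns to summarise and test.
#' @param group logical grouping column name.
#' @return data.frame with `variable`, `level`, `users_n`, `users_pct`,
#'   `nonusers_n`, `nonusers_pct`, `p`.
#' @export
table_one <- function(cohort, variables, group = "chm_user") {
  long <- summarize_by_group(cohort, variables, group)
  u <- long[long$group == "users", ]
  nu <- long[long$group == "nonusers", ]
  wide <- merge(u[, c("variable", "level", "count", "pct")],
                nu[, c("variable", "level", "count", "pct")],
                by = c("variable", "level"), suffixes = c("_u", "_n"))
  names(wide) <- c("variable", "level", "users_n", "users_pct",
                   "nonusers_n", "nonusers_pct")
  p <- vapply(variables, function(v) {
    compare_groups(cohort, v, group)$p_value
  }, 0)
  wide$p <- p[match(wide$variable, variables)]
  wide <- wide[order(match(wide$variable, variables), wide$level), ]
  rownames(wide) <- NULL
  wide
}
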