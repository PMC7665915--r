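# Ingredient screening and target-protein aggregation.

#' Screen ingredients by bioavailability and drug-likeness
#'
#' Retains rows with oral bioavailability strictly above `ob_min`,
#' drug-likeness strictly above `dl_min`, and an unset inorganic flag.
#' Both scores are fractions on `[0, 1]` by default; systems-pharmacology
#' databases that publish OB in percent are accommodated with
#' `ob_units = "percent"`, which divides the OB column by 100 before
#' filtering.
#'
#' @param table ingredient data.frame with columns `ob`, `dl` and
#'   optionally logical `inorganic` (absent means all organic).
#' @param ob_min,dl_min strict lower thresholds on `[0, 1]` (defaults
#'   0.30 and 0.18).
#' @param ob_units `"fraction"` (default) or `"percent"`.
#' @return the filtered data.frame (OB always on the fraction scale).
#' @export
filter_ingredients <- function(table, ob_min = 0.30, dl_min = 0.18,
                               ob_units = c("fraction", "percent")) {
  ob_units <- match.arg(ob_units)
  stopifnot(is.data.frame(table), all(c("ob", "dl") %in% names(table)),
            ob_min >= 0, ob_min <= 1, dl_min >= 0, dl_min <= 1)
  ob <- if (ob_units == "percent") table$ob / 100 else table$ob
  inorganic <- if (is.null(table$inorganic)) rep(FALSE, nrow(table)) else
    table$inorganic
  out <- table[ob > ob_min & table$dl > dl_min & !inorganic, , drop = FALSE]
  if (ob_units == "percent") out$ob <- out$ob / 100
  rownames(out) <- NULL
  out
}

#' Aggregate target proteins per network cluster
#'
#' A cluster's protein set is the union, over its member herbs, of the
#' targets of their retained ingredients.
#'
#' @param assignment a `cluster_assignment` (or named membership vector,
#'   herb -> cluster id).
#' @param herb_ingredients data.frame (`herb`, `ingredient`) linking herbs
#'   to their retained (filtered) ingredients.
#' @param target_map long data.frame (`agent`, `protein`).
#' @return named list, cluster id -> sorted character protein set. Herbs
#'   with no retained ingredient contribute an empty set with a warning.
#' @export
cluster_targets <- function(assignment, herb_ingredients, target_map) {
  memb <- if (inherits(assignment, "cluster_assignment")) {
    assignment$membership
  } else {
    assignment
  }
  stopifnot(!is.null(names(memb)))
  empty <- setdiff(names(memb), unique(herb_ingredients$herb))
  if (length(empty)) {
    warning("herb(s) with no retained ingredients: ",
            paste(empty, collapse = ", "))
  }
  tg_by_agent <- split(target_map$protein, target_map$agent)
  out <- lapply(sort(unique(memb)), function(k) {
    hh <- names(memb)[memb == k]
    ing <- herb_ingredients$ingredient[herb_ingredients$herb %in% hh]
    sort(unique(unlist(tg_by_agent[as.character(ing)], use.names = FALSE)))
  })
  names(out) <- sort(unique(memb))
  out
}

#' Aggregate target proteins per comparator category
#'
#' @param drug_categories data.frame (`drug`, `category`).
#' @param target_map long data.frame (`agent`, `protein`).
#' @return named list, category -> sorted protein set.
#' @export
comparator_targets <- function(drug_categories, target_map) {
  tg_by_agent <- split(target_map$protein, target_map$agent)
  cats <- sort(unique(drug_categories$category))
  out <- lapply(cats, function(cc) {
    dd <- drug_categories$drug[drug_categories$category == cc]
    sort(unique(unlist(tg_by_agent[as.character(dd)], use.names = FALSE)))
  })
  names(out) <- cats
  out
}

#' Overlap matrix between cluster and comparator target sets
#'
#' Cell (cluster, comparator) lists the sorted intersection of the two
#' protein sets, optionally restricted to a protein subset (for example
#' immune-annotated proteins); empty intersections render as an em dash.
#'
#' @param cluster_sets named list of protein sets (from
#'   [cluster_targets()]).
#' @param comparator_sets named list of protein sets.
#' @param protein_subset optional character vector restricting the
#'   intersections.
#' @return data.frame, one row per cluster with its set size (`n`) and one
#'   comma-joined column per comparator. The integer overlap counts are
#'   attached as attribute `"counts"`.
#' @export
overlap_table <- function(cluster_sets, comparator_sets,
                          protein_subset = NULL) {
  cells <- matrix("—", nrow = length(cluster_sets),
                  ncol = length(comparator_sets),
                  dimnames = list(names(cluster_sets),
                                  names(comparator_sets)))
  counts <- matrix(0L, nrow = length(cluster_sets),
                   ncol = length(comparator_sets),
                   dimnames = dimnames(cells))
  for (i in seq_along(cluster_sets)) {
    a <- cluster_sets[[i]]
    if (!is.null(protein_subset)) a <- intersect(a, protein_subset)
    for (j in seq_along(comparator_sets)) {
      b <- comparator_sets[[j]]
      if (!is.null(protein_subset)) b <- intersect(b, protein_subset)
      ov <- sort(intersect(a, b))
      counts[i, j] <- length(ov)
      if (length(ov)) cells[i, j] <- paste(ov, collapse = ", ")
    }
  }
  out <- data.frame(cluster = names(cluster_sets),
                    n = vapply(cluster_sets, length, 0L),
                    cells, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}
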