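#' Specification of a synthetic herb ingredient/target database
#'
#' Emulates the structure of systems-pharmacology ingredient tables: each
#' herb carries a number of chemical ingredients, each with an oral
#' bioavailability (OB) and drug-likeness (DL) score on `[0, 1]`, an
#' inorganic flag, and a set of putative protein targets.
#'
#' @param herbs character vector of herb codes.
#' @param ingredients_per_herb integer range `c(min, max)`; each herb's
#'   ingredient count is drawn uniformly from it.
#' @param ob_dist,dl_dist Beta shape parameters `c(alpha, beta)` for the
#'   OB and DL scores.
#' @param p_inorganic probability an ingredient is flagged inorganic.
#' @param proteins character vector, the protein universe targets are
#'   drawn from.
#' @param targets_per_ingredient integer range `c(min, max)` of targets
#'   per ingredient.
#' @param seed integer seed.
#' @return an object of class `ingredient_db_spec`.
#' @export
ingredient_db_spec <- function(herbs,
                               ingredients_per_herb = c(70L, 87L),
                               ob_dist = c(1.2, 2.2),
                               dl_dist = c(1.1, 4.0),
                               p_inorganic = 0.05,
                               proteins,
                               targets_per_ingredient = c(2L, 15L),
                               seed = 1L) {
  stopifnot(is.character(herbs), length(herbs) >= 1L,
            length(ingredients_per_herb) == 2L,
            ingredients_per_herb[1] >= 1L,
            ingredients_per_herb[1] <= ingredients_per_herb[2],
            length(ob_dist) == 2L, all(ob_dist > 0),
            length(dl_dist) == 2L, all(dl_dist > 0),
            p_inorganic >= 0, p_inorganic <= 1,
            length(targets_per_ingredient) == 2L,
            targets_per_ingredient[1] >= 1L,
            targets_per_ingredient[1] <= targets_per_ingredient[2])
  if (!is.character(proteins) || length(proteins) == 0L) {
    stop("protein universe must be a nonempty character vector",
         call. = FALSE)
  }
  structure(list(herbs = herbs,
                 ingredients_per_herb = as.integer(ingredients_per_herb),
                 ob_dist = ob_dist, dl_dist = dl_dist,
                 p_inorganic = p_inorganic, proteins = proteins,
                 targets_per_ingredient = as.integer(targets_per_ingredient),
                 seed = as.integer(seed)),
            class = "ingredient_db_spec")
}

#' Generate a synthetic ingredient table and target map
#'
#' @param spec an [ingredient_db_spec()].
#' @return list with `ingredients` (data.frame: `herb`, `ingredient`,
#'   `ob`, `dl`, logical `inorganic`) and `targets` (long data.frame:
#'   `agent`, `protein`, one row per ingredient-target link). Identical
#'   spec and seed give identical tables.
#' @export
generate_ingredient_db <- function(spec) {
  stopifnot(inherits(spec, "ingredient_db_spec"))
  with_seed(derive_seed(spec$seed, "ingredients"), {
    rng <- spec$ingredients_per_herb
    n_ing <- rng[1] + sample.int(rng[2] - rng[1] + 1L,
                                 length(spec$herbs), replace = TRUE) - 1L
    herb_col <- rep(spec$herbs, n_ing)
    total <- sum(n_ing)
    ing_id <- sprintf("ING%05d", seq_len(total))
    tab <- data.frame(
      herb = herb_col,
      ingredient = ing_id,
      ob = rbeta(total, spec$ob_dist[1], spec$ob_dist[2]),
      dl = rbeta(total, spec$dl_dist[1], spec$dl_dist[2]),
      inorganic = runif(total) < spec$p_inorganic,
      stringsAsFactors = FALSE
    )
    trng <- spec$targets_per_ingredient
    k <- trng[1] + sample.int(trng[2] - trng[1] + 1L, total,
                              replace = TRUE) - 1L
    k <- pmin(k, length(spec$proteins))
    tg <- lapply(k, function(ki) {
      spec$proteins[sample.int(length(spec$proteins), ki)]
    })
    targets <- data.frame(agent = rep(ing_id, lengths(tg)),
                          protein = unlist(tg), stringsAsFactors = FALSE)
  })
  list(ingredients = tab, targets = targets)
}

#' Generate a synthetic pathway collection
#'
#' Builds a GMT-writable collection of protein sets with a two-level
#' category path per pathway (for example `"Immune System/Innate Immune
#' System"`).
#'
#' @param n_pathways number of pathways.
#' @param size_range integer `c(min, max)` pathway size.
#' @param universe character protein universe the collection is annotated
#'   against.
#' @param categories category paths to assign: a named probability vector
#'   (paths sampled with those weights), an unnamed vector of length
#'   `n_pathways` (assigned in order), or a shorter unnamed vector
#'   (sampled uniformly).
#' @param seed integer seed.
#' @param member_pool optional character subset of `universe` to draw
#'   members from (used to plant coverage structure); defaults to the
#'   whole universe.
#' @param prefix pathway-name prefix.
#' @return an object of class `pathway_collection`: list with `pathways`
#'   (named list of member vectors), `categories` (named character) and
#'   `universe`.
#' @export
generate_pathways <- function(n_pathways, size_range, universe, categories,
                              seed = 1L, member_pool = NULL,
                              prefix = "PW") {
  n_pathways <- check_count(n_pathways, "n_pathways")
  if (length(universe) == 0L) stop("universe must be nonempty", call. = FALSE)
  member_pool <- member_pool %||% universe
  if (!all(member_pool %in% universe)) {
    stop("member_pool must be a subset of the universe", call. = FALSE)
  }
  stopifnot(length(size_range) == 2L, size_range[1] >= 1L,
            size_range[1] <= size_range[2])
  if (size_range[2] > length(member_pool)) {
    stop("size_range exceeds the available pool (",
         length(member_pool), " proteins)", call. = FALSE)
  }
  with_seed(derive_seed(seed, "pathways"), {
    sizes <- size_range[1] +
      sample.int(size_range[2] - size_range[1] + 1L, n_pathways,
                 replace = TRUE) - 1L
    pw <- lapply(sizes, function(k) {
      sort(member_pool[sample.int(length(member_pool), k)])
    })
    names(pw) <- sprintf("%s%04d", prefix, seq_len(n_pathways))
    cats <- if (is.null(names(categories)) &&
                length(categories) == n_pathways) {
      categories
    } else if (!is.null(names(categories))) {
      sample(names(categories), n_pathways, replace = TRUE,
             prob = categories)
    } else {
      sample(categories, n_pathways, replace = TRUE)
    }
    names(cats) <- names(pw)
  })
  pathway_collection(pw, cats, universe)
}

#' Construct a pathway collection
#'
#' @param pathways named list of protein-member character vectors.
#' @param categories named character vector of category paths, names
#'   matching `pathways`.
#' @param universe character protein universe; defaults to the union of
#'   all members.
#' @return a `pathway_collection`.
#' @export
pathway_collection <- function(pathways, categories = NULL,
                               universe = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)),
            !anyDuplicated(names(pathways)))
  universe <- universe %||% sort(unique(unlist(pathways)))
  bad <- !vapply(pathways, function(m) all(m %in% universe), TRUE)
  if (any(bad)) {
    stop("pathway members outside the universe: ",
         paste(names(pathways)[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- stats::setNames(rep(NA_character_, length(pathways)),
                                  names(pathways))
  }
  stopifnot(all(names(pathways) %in% names(categories)))
  structure(list(pathways = pathways,
                 categories = categories[names(pathways)],
                 universe = universe),
            class = "pathway_collection")
}

#' Concatenate pathway collections
#'
#' @param ... `pathway_collection` objects with disjoint pathway names.
#' @return a single `pathway_collection` over the union of the universes.
#' @export
combine_collections <- function(...) {
  colls <- list(...)
  stopifnot(all(vapply(colls, inherits, TRUE, "pathway_collection")))
  pw <- do.call(c, lapply(colls, `[[`, "pathways"))
  if (anyDuplicated(names(pw))) stop("duplicate pathway names", call. = FALSE)
  cats <- do.call(c, lapply(colls, `[[`, "categories"))
  uni <- sort(unique(unlist(lapply(colls, `[[`, "universe"))))
  pathway_collection(pw, cats, uni)
}
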