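#' Specification of a transaction generator with planted herb communities
#'
#' Describes a market-basket style prescription generator whose
#' co-prescription structure is known by construction: herbs are organised
#' into clusters, each with a designated core herb that appears in every
#' transaction drawn from that cluster, and the remaining items are filled
#' from the cluster's members or from a background pool. The planted
#' partition is the ground truth against which community detection is
#' evaluated.
#'
#' @param clusters list of clusters, each a list with `herbs` (character,
#'   at least two codes), `core` (one of `herbs`) and optionally `co_draw`
#'   (per-slot probability that a filler item comes from the cluster's own
#'   members; default 0.8).
#' @param background_herbs character vector of herbs outside any cluster.
#' @param size_dist named probability vector over transaction sizes; names
#'   are the integer sizes. Default digitizes a right-skewed distribution
#'   with mode 5, mean about 5.6 and 6.3 percent of mass at sizes of ten
#'   or more.
#' @param n_prescriptions number of transactions to draw.
#' @param cluster_weights probability vector over clusters (default equal).
#' @param background_mass relative weight of the background pool when
#'   filling a slot: each filler is drawn from the cluster's members vs
#'   the background pool with odds `co_draw : background_mass` (so the
#'   defaults 0.8 and 0.05 give about one background herb per seventeen
#'   fillers). Background herbs never form planted structure.
#' @param cluster_mixing per-slot probability that a filler item is drawn
#'   from another cluster's members; 0 (the default) keeps transactions
#'   within one cluster, matching largely disjoint observed communities.
#' @param seed integer seed.
#' @return an object of class `planted_network_spec`.
#' @seealso [generate_prescriptions()], [ar_network_spec()]
#' @export
planted_network_spec <- function(clusters,
                                 background_herbs = character(),
                                 size_dist = default_size_dist(),
                                 n_prescriptions = 20000,
                                 cluster_weights = NULL,
                                 background_mass = 0.05,
                                 cluster_mixing = 0,
                                 seed = 1L) {
  stopifnot(is.list(clusters), length(clusters) >= 1L)
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    if (!is.list(cl) || is.null(cl$herbs) || is.null(cl$core)) {
      stop("cluster ", i, " must list 'herbs' and 'core'", call. = FALSE)
    }
    if (length(cl$herbs) < 2L) {
      stop("cluster ", i, " must contain at least 2 herbs", call. = FALSE)
    }
    if (!cl$core %in% cl$herbs) {
      stop("core of cluster ", i, " ('", cl$core,
           "') is not among its members", call. = FALSE)
    }
    clusters[[i]]$co_draw <- cl$co_draw %||% 0.8
    stopifnot(clusters[[i]]$co_draw >= 0, clusters[[i]]$co_draw <= 1)
  }
  all_herbs <- c(unlist(lapply(clusters, `[[`, "herbs")), background_herbs)
  if (anyDuplicated(all_herbs)) {
    stop("herb codes must be unique across clusters and background: ",
         paste(unique(all_herbs[duplicated(all_herbs)]), collapse = ", "),
         call. = FALSE)
  }
  check_prob_vector(size_dist, "size_dist")
  if (is.null(names(size_dist))) {
    names(size_dist) <- seq_along(size_dist)
  }
  sizes <- as.integer(names(size_dist))
  if (max(sizes[size_dist > 0]) > length(all_herbs)) {
    stop("size_dist allows transactions of size ",
         max(sizes[size_dist > 0]), " but only ", length(all_herbs),
         " distinct herbs exist", call. = FALSE)
  }
  if (is.null(cluster_weights)) {
    cluster_weights <- rep(1 / length(clusters), length(clusters))
  }
  check_prob_vector(cluster_weights, "cluster_weights")
  stopifnot(length(cluster_weights) == length(clusters),
            background_mass >= 0, background_mass <= 1,
            cluster_mixing >= 0, cluster_mixing <= 1)
  if (background_mass > 0 && length(background_herbs) == 0L) {
    stop("background_mass > 0 requires background herbs", call. = FALSE)
  }
  if (background_mass + max(vapply(clusters, `[[`, 0, "co_draw")) <= 0) {
    stop("co_draw and background_mass cannot both be zero", call. = FALSE)
  }
  structure(list(clusters = clusters, background_herbs = background_herbs,
                 size_dist = size_dist, n_prescriptions =
                   check_count(n_prescriptions, "n_prescriptions"),
                 cluster_weights = cluster_weights,
                 background_mass = background_mass,
                 cluster_mixing = cluster_mixing, seed = as.integer(seed)),
            class = "planted_network_spec")
}

#' Default transaction-size distribution
#'
#' Right-skewed distribution over 1..15 herbs per prescription with mode 5
#' (17 percent of mass), mean 5.63 and 6.3 percent of mass at ten or more
#' items, the tail split geometrically with ratio one half.
#'
#' @return named probability vector.
#' @export
default_size_dist <- function() {
  body <- c(`1` = .035, `2` = .058, `3` = .100, `4` = .149, `5` = .170,
            `6` = .151, `7` = .118, `8` = .089, `9` = .067)
  tail <- c(`10` = .032, `11` = .016, `12` = .008, `13` = .004,
            `14` = .002, `15` = .001)
  c(body, tail)
}

#' Generate prescription transactions with planted communities
#'
#' For each transaction a size is drawn from the spec's size distribution,
#' a cluster is picked with the configured weight, its core herb is always
#' included, and every remaining slot is filled (sampling without
#' replacement) from the cluster's members or the background pool with
#' relative odds `co_draw : background_mass`; once the cluster's members
#' are exhausted, fillers come from the background. No herb is repeated
#' within a transaction.
#'
#' @param spec a [planted_network_spec()].
#' @return a data.frame with `prescription_id`, `patient_id`, a
#'   pipe-delimited `herbs` field and the index of the generating cluster
#'   (`truth_cluster`). The attribute `herb_cluster` maps every planted
#'   herb to its ground-truth cluster.
#' @export
generate_prescriptions <- function(spec) {
  stopifnot(inherits(spec, "planted_network_spec"))
  n <- spec$n_prescriptions
  sizes_lev <- as.integer(names(spec$size_dist))
  members <- lapply(spec$clusters, function(cl) setdiff(cl$herbs, cl$core))
  cores <- vapply(spec$clusters, `[[`, "", "core")
  co_draw <- vapply(spec$clusters, `[[`, 0, "co_draw")
  bg <- spec$background_herbs
  other_pool <- lapply(seq_along(spec$clusters), function(i) {
    unlist(lapply(spec$clusters[-i], `[[`, "herbs"))
  })
  pick <- function(pool, k) pool[sample.int(length(pool), k)]

  # per-cluster odds that a filler slot draws a member vs background
  p_member <- ifelse(co_draw + spec$background_mass > 0,
                     co_draw / (co_draw + spec$background_mass), 1)

  with_seed(derive_seed(spec$seed, "prescriptions"), {
    size <- sizes_lev[sample.int(length(sizes_lev), n, replace = TRUE,
                                 prob = spec$size_dist)]
    cl_of <- sample.int(length(spec$clusters), n, replace = TRUE,
                        prob = spec$cluster_weights)
    herbs <- character(n)
    for (i in seq_len(n)) {
      s <- size[i]
      k <- cl_of[i]
      items <- cores[k]
      n_fill <- s - 1L
      if (n_fill > 0L) {
        u_mix <- runif(n_fill) < spec$cluster_mixing
        n_mix <- min(sum(u_mix), length(other_pool[[k]]))
        mixed <- if (n_mix > 0L) pick(other_pool[[k]], n_mix) else character()
        rest <- n_fill - n_mix
        n_cl <- min(sum(runif(rest) < p_member[k]), length(members[[k]]))
        from_cl <- if (n_cl > 0L) pick(members[[k]], n_cl) else character()
        n_bg <- rest - n_cl
        from_bg <- pick(bg, min(n_bg, length(bg)))
        items <- c(items, from_cl, mixed, from_bg)
        if (length(items) < s) {  # pools exhausted; top up anywhere
          pool <- setdiff(c(unlist(members), bg), items)
          items <- c(items, pick(pool, s - length(items)))
        }
      }
      herbs[i] <- paste(sort(items), collapse = "|")
    }
    n_pat <- max(1L, as.integer(round(n / 6.6)))
    patient <- sprintf("P%06d", sample.int(n_pat, n, replace = TRUE))
    out <- data.frame(prescription_id = sprintf("RX%07d", seq_len(n)),
                      patient_id = patient, herbs = herbs,
                      truth_cluster = cl_of, stringsAsFactors = FALSE)
  })
  truth <- rep(seq_along(spec$clusters),
               vapply(spec$clusters, function(cl) length(cl$herbs), 1L))
  names(truth) <- unlist(lapply(spec$clusters, `[[`, "herbs"))
  attr(out, "herb_cluster") <- truth
  out
}

# Split the pipe-delimited herbs field into a list of character vectors.
herb_list <- function(prescriptions) {
  strsplit(prescriptions$herbs, "|", fixed = TRUE)
}
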