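# Co-prescription network: construction, degree centrality, greedy
# modularity clustering with a deterministic tie-break, core-herb rule.

#' Build the co-prescription network from association rules
#'
#' One undirected edge per unordered herb pair; duplicate directions
#' collapse to a single edge carrying the pair support, the confidence of
#' the higher-confidence direction, and the (direction-symmetric) lift.
#' Node prevalence (single-herb support, percent) is attached either from
#' `prevalence` or recovered from the rule metrics themselves
#' (`support(antecedent) = 100 * support_pair / confidence`); nodes whose
#' prevalence cannot be established are flagged `NA`.
#'
#' @param rules data.frame from [mine_pair_rules()] or [top_rules()].
#' @param prevalence optional named numeric vector of single-herb supports
#'   (percent), or data.frame with columns `herb`, `prevalence`.
#' @param herb_type_map optional data.frame (`herb`, `type`) attached as a
#'   node attribute.
#' @return an `igraph` object with node attributes `prevalence`, `type`
#'   and edge attributes `support`, `confidence`, `lift`.
#' @export
build_network <- function(rules, prevalence = NULL, herb_type_map = NULL) {
  if (nrow(rules) == 0L) stop("no rules to build a network from",
                              call. = FALSE)
  edges <- top_rules(rules, n = nrow(rules), collapse_direction = TRUE)
  from <- pmin(edges$antecedent, edges$consequent)
  to <- pmax(edges$antecedent, edges$consequent)
  nodes <- sort(unique(c(from, to)))

  prev <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  # recover marginal supports from the rule identities
  impl_a <- 100 * edges$support / edges$confidence
  impl_b <- edges$confidence / edges$lift
  for (i in seq_len(nrow(edges))) {
    prev[edges$antecedent[i]] <- impl_a[i]
    prev[edges$consequent[i]] <- impl_b[i]
  }
  if (!is.null(prevalence)) {
    if (is.data.frame(prevalence)) {
      prevalence <- stats::setNames(prevalence$prevalence, prevalence$herb)
    }
    hit <- intersect(nodes, names(prevalence))
    prev[hit] <- prevalence[hit]
  }
  type <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  if (!is.null(herb_type_map)) {
    idx <- match(nodes, herb_type_map$herb)
    type[!is.na(idx)] <- as.character(herb_type_map$type[idx[!is.na(idx)]])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, support = edges$support,
               confidence = edges$confidence, lift = edges$lift,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, prevalence = as.numeric(prev),
                          type = as.character(type),
                          stringsAsFactors = FALSE))
  g
}

#' Degree centrality
#'
#' Raw degree counts (number of incident edges, not normalized).
#'
#' @param network an `igraph` network.
#' @return named integer vector, node -> degree.
#' @export
degree_centrality <- function(network) {
  d <- igraph::degree(network, loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(network)$name)
}

# Weighted modularity of a membership vector (named by node).
network_modularity <- function(network, membership,
                               weights = igraph::E(network)$support) {
  igraph::modularity(network,
                     membership = as.integer(factor(
                       membership[igraph::V(network)$name])),
                     weights = weights)
}

#' Detect clusters by greedy modularity agglomeration
#'
#' Connected components are split first; within each component an
#' agglomerative (Clauset-Newman-Moore style) search merges, at every
#' step, the pair of connected clusters with the largest modularity gain,
#' breaking ties toward the lexicographically smallest cluster pair (each
#' cluster identified by its smallest member name). The partition with
#' maximal weighted modularity along the merge trajectory is returned, so
#' isolated dyads form their own clusters. The procedure is fully
#' deterministic and invariant to node order. Edge weight defaults to the
#' pair support.
#'
#' @param network an `igraph` network.
#' @param method `"greedy"` (the deterministic agglomeration) or
#'   `"louvain"` (igraph's multilevel algorithm, provided for comparison).
#' @param weights edge weights (default the `support` edge attribute;
#'   `NULL` for unweighted).
#' @return list of class `cluster_assignment`: `membership` (named integer,
#'   cluster ids ordered by decreasing cluster size then smallest member),
#'   `modularity` (weighted Q of the partition), `labels` (free-text
#'   per-cluster labels, `NA` until annotated).
#' @export
detect_clusters <- function(network, method = c("greedy", "louvain"),
                            weights = igraph::E(network)$support) {
  method <- match.arg(method)
  if (igraph::vcount(network) == 0L) stop("empty network", call. = FALSE)
  if (method == "louvain") {
    cl <- igraph::cluster_louvain(network, weights = weights)
    memb <- stats::setNames(as.integer(igraph::membership(cl)),
                            igraph::V(network)$name)
  } else {
    memb <- greedy_modularity(network, weights)
  }
  memb <- canonical_clusters(memb)
  q <- network_modularity(network, memb, weights)
  structure(list(membership = memb, modularity = q,
                 labels = stats::setNames(
                   rep(NA_character_, max(memb)), seq_len(max(memb)))),
            class = "cluster_assignment")
}

# Deterministic CNM-style agglomeration. Returns a named membership
# vector keyed by the smallest member name of each cluster.
greedy_modularity <- function(network, weights) {
  nodes <- sort(igraph::V(network)$name)
  el <- igraph::as_data_frame(network, what = "edges")
  w <- if (is.null(weights)) rep(1, nrow(el)) else weights
  m2 <- 2 * sum(w)                                     # 2m
  # node strength
  strength <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(el))) {
    strength[el$from[i]] <- strength[el$from[i]] + w[i]
    strength[el$to[i]] <- strength[el$to[i]] + w[i]
  }
  # cluster state: keyed by smallest member name
  memb <- stats::setNames(nodes, nodes)   # node -> cluster key
  a <- strength / m2                      # cluster key -> a_c
  # e[key1][key2]: fraction of weight between clusters (w/m2, symmetric)
  e <- new.env(parent = emptyenv())
  ekey <- function(k1, k2) paste(min(k1, k2), max(k1, k2), sep = "\r")
  for (i in seq_len(nrow(el))) {
    k <- ekey(el$from[i], el$to[i])
    assign(k, (if (exists(k, e)) get(k, e) else 0) + w[i] / m2, envir = e)
  }
  best <- memb
  best_q <- sum(vapply(unique(memb), function(k) {
    self <- ekey(k, k)
    (if (exists(self, e)) get(self, e) else 0) - a[k]^2
  }, 0))
  cur_q <- best_q
  comp <- igraph::components(network)$membership[nodes]

  for (cid in sort(unique(comp))) {
    repeat {
      keys <- sort(unique(memb[names(comp)[comp == cid]]))
      if (length(keys) < 2L) break
      # candidate merges: connected cluster pairs
      best_dq <- -Inf; best_pair <- NULL
      for (i in seq_along(keys)) {
        for (j in seq_len(i - 1L)) {
          k1 <- keys[j]; k2 <- keys[i]
          kk <- ekey(k1, k2)
          if (!exists(kk, e)) next
          dq <- 2 * (get(kk, e) - a[k1] * a[k2])
          if (dq > best_dq + 1e-12 ||
              (abs(dq - best_dq) <= 1e-12 && !is.null(best_pair) &&
               (k1 < best_pair[1] ||
                (k1 == best_pair[1] && k2 < best_pair[2])))) {
            best_dq <- dq; best_pair <- c(k1, k2)
          }
        }
      }
      if (is.null(best_pair)) break
      k1 <- best_pair[1]; k2 <- best_pair[2]   # k1 < k2; k1 survives
      # merge k2 into k1: update e entries
      for (k in unique(memb)) {
        if (k == k2) next
        kk2 <- ekey(k2, if (k == k1) k2 else k)
        tgt <- ekey(k1, if (k == k1) k1 else k)
        if (k == k1) {                    # within-cluster weight
          add <- (if (exists(ekey(k2, k2), e)) get(ekey(k2, k2), e) else 0) +
            (if (exists(ekey(k1, k2), e)) get(ekey(k1, k2), e) else 0)
          if (add > 0) {
            assign(ekey(k1, k1),
                   (if (exists(ekey(k1, k1), e)) get(ekey(k1, k1), e)
                    else 0) + add, envir = e)
          }
        } else if (exists(kk2, e)) {
          assign(tgt, (if (exists(tgt, e)) get(tgt, e) else 0) +
                   get(kk2, e), envir = e)
          rm(list = kk2, envir = e)
        }
      }
      if (exists(ekey(k1, k2), e)) rm(list = ekey(k1, k2), envir = e)
      a[k1] <- a[k1] + a[k2]
      a <- a[names(a) != k2]
      memb[memb == k2] <- k1
      cur_q <- cur_q + best_dq
      if (cur_q > best_q + 1e-12) {
        best_q <- cur_q
        best <- memb
      }
    }
  }
  best
}

# Renumber cluster keys to 1..k, largest cluster first (ties: smallest
# member name), and order the vector by node name.
canonical_clusters <- function(memb) {
  memb <- memb[sort(names(memb))]
  sizes <- table(memb)
  keys <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  out <- stats::setNames(match(memb, keys), names(memb))
  out
}

#' Identify the core herb of each cluster
#'
#' Operationalizes the qualitative criterion that herbs with higher
#' prevalence and higher degree centrality play the more central role:
#' per cluster, the herb maximizing degree, then prevalence, then the
#' lexicographically smallest name.
#'
#' @param network an `igraph` network with a `prevalence` node attribute.
#' @param assignment a `cluster_assignment` from [detect_clusters()].
#' @return named character vector, cluster id -> core herb.
#' @export
identify_core <- function(network, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  memb <- assignment$membership
  deg <- degree_centrality(network)
  prev <- stats::setNames(igraph::V(network)$prevalence,
                          igraph::V(network)$name)
  if (!all(names(deg) %in% names(memb))) {
    stop("assignment does not cover the network", call. = FALSE)
  }
  ids <- sort(unique(memb))
  stats::setNames(vapply(ids, function(k) {
    nn <- names(memb)[memb == k]
    pv <- ifelse(is.na(prev[nn]), -Inf, prev[nn])
    ord <- order(-deg[nn], -pv, nn)
    nn[ord[1]]
  }, ""), ids)
}

#' Cluster table for export
#'
#' @param network an `igraph` network.
#' @param assignment a `cluster_assignment`.
#' @return data.frame with `herb`, `cluster`, `degree`, `prevalence`,
#'   `is_core`, `label`.
#' @export
cluster_table <- function(network, assignment) {
  memb <- assignment$membership
  core <- identify_core(network, assignment)
  deg <- degree_centrality(network)
  prev <- stats::setNames(igraph::V(network)$prevalence,
                          igraph::V(network)$name)
  nn <- names(memb)
  data.frame(herb = nn, cluster = as.integer(memb),
             degree = as.integer(deg[nn]), prevalence = as.numeric(prev[nn]),
             is_core = nn == core[as.character(memb)],
             label = as.character(assignment$labels[as.character(memb)]),
             stringsAsFactors = FALSE)
}
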