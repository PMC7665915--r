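# End-to-end demo pipeline and planted-structure recovery evaluation.

#' Run the full demo pipeline
#'
#' Chains every stage on the synthetic AR study conditions: cohort
#' simulation and table-one summary, transaction simulation, rule mining
#' and top-rule selection, network construction and clustering with core
#' herbs, ingredient screening and cluster target aggregation, and
#' overrepresentation analysis with coverage comparison. All artifacts
#' are written under `outdir`; reruns with the same config are
#' byte-identical.
#'
#' @param config pipeline configuration (see [default_config()]); a path
#'   to a YAML file is also accepted.
#' @param outdir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  meta <- paste0("chmnet ", as.character(utils::packageVersion("chmnet")),
                 " seed=", config$seed)
  p <- function(f) file.path(outdir, f)

  say("simulate: cohort")
  cohort <- generate_cohort(ar_cohort_spec(seed = config$seed))
  write_csv_c(cohort, p("cohort.csv"), meta)
  say("  ", nrow(cohort), " patients")

  say("simulate: prescriptions")
  spec <- ar_network_spec(n_prescriptions = config$n_prescriptions,
                          seed = config$seed)
  px <- generate_prescriptions(spec)
  write_prescriptions(px, p("prescriptions.csv"), comments = meta)
  say("  ", nrow(px), " prescriptions, mean size ",
      round(mean_prescription_size(px), 2))

  say("cohort: table one")
  vars <- setdiff(names(cohort), c("patient_id", "chm_user"))
  t1 <- table_one(cohort, vars)
  write_csv_c(t1, p("table_one.csv"), meta)

  say("mine: association rules")
  rules <- mine_pair_rules(px, config$min_support, config$min_confidence,
                           config$min_lift)
  if (nrow(rules) == 0L) warning("no rules passed the thresholds")
  top <- top_rules(rules, config$top_n)
  write_csv_c(top, p("rules_top.csv"), meta)
  prev <- prevalence_ranking(px, ar_herb_types())
  write_csv_c(prev, p("prevalence.csv"), meta)
  say("  ", nrow(rules), " directed rules, top ", nrow(top), " pairs kept")

  say("network: build + cluster")
  net <- build_network(top, prevalence = prev, herb_type_map = ar_herb_types())
  asg <- detect_clusters(net, method = config$cluster_method)
  labels <- ar_cluster_labels()
  truth <- attr(px, "herb_cluster")
  for (k in sort(unique(asg$membership))) {
    nn <- names(asg$membership)[asg$membership == k]
    tt <- truth[intersect(nn, names(truth))]
    if (length(tt)) {
      asg$labels[as.character(k)] <-
        labels[as.integer(names(sort(-table(tt)))[1])]
    }
  }
  ct <- cluster_table(net, asg)
  write_csv_c(ct, p("clusters.csv"), meta)
  write_network(net, p("network_edges.tsv"), p("network.graphml"), asg)
  say("  ", igraph::vcount(net), " nodes, ", igraph::ecount(net),
      " edges, ", max(asg$membership), " clusters, Q = ",
      round(asg$modularity, 3))

  say("pharm: ingredient screening + cluster targets")
  fx <- ar_pharm_fixture(seed = config$seed)
  write_csv_c(fx$ingredient_db$ingredients, p("ingredients.csv"), meta)
  kept <- filter_ingredients(fx$ingredient_db$ingredients,
                             config$ob_min, config$dl_min,
                             ob_units = config$ob_units)
  write_csv_c(kept, p("ingredients_filtered.csv"), meta)
  cl_sets <- suppressWarnings(
    cluster_targets(asg, kept, fx$ingredient_db$targets))
  wm_sets <- comparator_targets(fx$wm$drugs, fx$wm$targets)
  ov <- overlap_table(cl_sets, wm_sets, fx$immune_proteins)
  write_csv_c(ov, p("overlap_immune.csv"), meta)
  say("  ", nrow(kept), " of ", nrow(fx$ingredient_db$ingredients),
      " ingredients retained")

  say("enrich: overrepresentation analysis")
  write_gmt(fx$collection, p("pathways.gmt"))
  chm_targets <- sort(unique(unlist(cl_sets)))
  wm_targets <- sort(unique(unlist(wm_sets)))
  res_chm <- run_ora(chm_targets, fx$collection, alpha = config$alpha,
                     method = config$correction)
  res_wm <- run_ora(wm_targets, fx$collection, alpha = config$alpha,
                    method = config$correction)
  write_csv_c(res_chm, p("enrichment_chm.csv"), meta)
  write_csv_c(res_wm, p("enrichment_wm.csv"), meta)
  cov <- compare_coverage(list(chm = res_chm, wm = res_wm),
                          category_filter = "Immune System")
  counts_df <- data.frame(category = rownames(cov$counts), cov$counts,
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write_csv_c(counts_df, p("coverage_immune.csv"), meta)
  say("  covered pathways: chm ", sum(res_chm$covered), ", wm ",
      sum(res_wm$covered))

  yaml::write_yaml(config, p("config_echo.yaml"))
  invisible(list(cohort = cohort, prescriptions = px, table_one = t1,
                 rules = rules, top = top, prevalence = prev,
                 network = net, assignment = asg, clusters = ct,
                 ingredients_kept = kept, cluster_sets = cl_sets,
                 wm_sets = wm_sets, overlap = ov,
                 enrichment = list(chm = res_chm, wm = res_wm),
                 coverage = cov, config = config))
}

#' Evaluate recovery of the planted communities
#'
#' For each seed, generates transactions from the planted spec, mines the
#' pair rules, keeps the top pairs, builds the network, detects clusters,
#' and scores (a) the adjusted Rand index between the detected partition
#' and the planted one, computed over the planted (non-background) herbs
#' present in the network, and (b) whether each planted cluster's core
#' herb is the identified core of the detected cluster containing it.
#'
#' @param seeds integer vector of generator seeds.
#' @param spec_fun function(seed) returning a [planted_network_spec()];
#'   defaults to [ar_network_spec()] with its acceptance-fixture settings.
#' @param config mining/clustering parameters (see [default_config()]).
#' @return data.frame with one row per seed: `seed`, `ari`, `n_clusters`,
#'   `cores_found`, `cores_total`.
#' @export
planted_recovery <- function(seeds,
                             spec_fun = function(s) ar_network_spec(seed = s),
                             config = default_config()) {
  config <- validate_config(config)
  rows <- lapply(seeds, function(s) {
    spec <- spec_fun(s)
    px <- generate_prescriptions(spec)
    rules <- mine_pair_rules(px, config$min_support, config$min_confidence,
                             config$min_lift)
    net <- build_network(top_rules(rules, config$top_n))
    asg <- detect_clusters(net, method = config$cluster_method)
    truth <- attr(px, "herb_cluster")
    common <- intersect(names(truth), names(asg$membership))
    ari <- mclust::adjustedRandIndex(truth[common], asg$membership[common])
    cores <- identify_core(net, asg)
    planted_cores <- vapply(spec$clusters, `[[`, "", "core")
    in_net <- planted_cores %in% names(asg$membership)
    found <- vapply(planted_cores[in_net], function(h) {
      k <- asg$membership[h]
      identical(unname(cores[as.character(k)]), h)
    }, TRUE)
    data.frame(seed = s, ari = ari, n_clusters = max(asg$membership),
               cores_found = sum(found), cores_total = sum(in_net))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
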