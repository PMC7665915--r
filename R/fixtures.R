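# Default study conditions for the allergic-rhinitis (AR) demo: published
# count tables for the user/nonuser cohort, a planted six-community
# co-prescription structure whose cores and prevalences mirror the herbs
# most commonly prescribed for AR in Taiwan's insurance system, and a
# synthetic systems-pharmacology side (ingredients, targets, pathways)
# with planted pathway-coverage structure.

#' Published user/nonuser count table for the AR cohort
#'
#' Per-variable level counts for herbal-medicine users (n = 33,507) and
#' nonusers (n = 55,641) among allergic-rhinitis patients, as printed in
#' the source count table shipped with the package. Flag variables carry
#' a single `"yes"` row.
#'
#' @return data.frame with `variable`, `level`, `users`, `nonusers`.
#' @export
ar_cohort_counts <- function() {
  read_csv_c(system.file("extdata", "ar_cohort_counts.csv",
                         package = "chmnet", mustWork = TRUE))
}

#' Expand a count table into a row-level cohort
#'
#' Builds a patient-level cohort whose per-group marginals reproduce the
#' given counts exactly. Variables are expanded independently (the joint
#' distribution is product-form, which is immaterial for marginal
#' summaries and per-variable tests). Flag rows (`level == "yes"`) become
#' logical columns.
#'
#' @param counts data.frame as returned by [ar_cohort_counts()].
#' @return cohort data.frame with `patient_id`, `chm_user` and one column
#'   per variable.
#' @export
cohort_from_counts <- function(counts) {
  stopifnot(all(c("variable", "level", "users", "nonusers") %in%
                  names(counts)))
  first <- counts[counts$variable == counts$variable[1], ]
  is_flag <- function(d) nrow(d) == 1L && d$level == "yes"
  sizes <- if (is_flag(first)) {
    stop("the first variable must be an exhaustive categorical so group ",
         "sizes can be derived", call. = FALSE)
  } else {
    c(users = sum(first$users), nonusers = sum(first$nonusers))
  }
  out <- data.frame(
    patient_id = sprintf("P%07d", seq_len(sum(sizes))),
    chm_user = rep(c(TRUE, FALSE), sizes), stringsAsFactors = FALSE)
  for (v in unique(counts$variable)) {
    d <- counts[counts$variable == v, ]
    if (is_flag(d)) {
      out[[v]] <- c(rep(c(TRUE, FALSE), c(d$users, sizes["users"] - d$users)),
                    rep(c(TRUE, FALSE),
                        c(d$nonusers, sizes["nonusers"] - d$nonusers)))
    } else {
      stopifnot(sum(d$users) == sizes["users"],
                sum(d$nonusers) == sizes["nonusers"])
      out[[v]] <- c(rep(d$level, d$users), rep(d$level, d$nonusers))
    }
  }
  out
}

#' Default cohort generator spec for the AR demo
#'
#' Per-group category probabilities are the observed proportions from
#' [ar_cohort_counts()]; group sizes default to the published 33,507
#' users and 55,641 nonusers.
#'
#' @param n_users,n_nonusers group sizes.
#' @param seed integer seed.
#' @return a [cohort_spec()].
#' @export
ar_cohort_spec <- function(n_users = 33507, n_nonusers = 55641, seed = 1L) {
  counts <- ar_cohort_counts()
  sz_u <- sum(counts$users[counts$variable == "gender"])
  sz_n <- sum(counts$nonusers[counts$variable == "gender"])
  probs <- lapply(unique(counts$variable), function(v) {
    d <- counts[counts$variable == v, ]
    if (nrow(d) == 1L && d$level == "yes") {
      list(users = d$users / sz_u, nonusers = d$nonusers / sz_n)
    } else {
      # normalize by the column sum (printed tables can be off by a
      # rounding unit relative to the group size)
      list(users = stats::setNames(d$users / sum(d$users), d$level),
           nonusers = stats::setNames(d$nonusers / sum(d$nonusers),
                                      d$level))
    }
  })
  names(probs) <- unique(counts$variable)
  cohort_spec(n_users, n_nonusers, probs, seed = seed)
}

# Herb rosters of the six planted communities. Clusters 1-2 are built
# around the two dominant herbal formulas, 3-4 around common single
# herbs, and 5-6 are the isolated "drug pair" dyads.
ar_cluster_rosters <- function() {
  list(
    list(label = "wind-heat syndrome",
         core = "Xin-Yi-Qing-Fei-Tang",
         herbs = c("Xin-Yi-Qing-Fei-Tang", "Houttuynia cordata",
                   "Xanthium sibiricum", "Scutellaria baicalensis",
                   "Cang-Er-San", "Mentha haplocalyx",
                   "Gardenia jasminoides", "Eriobotrya japonica")),
    list(label = "wind-cold-dampness syndrome",
         core = "Xiao-Qing-Long-Tang",
         herbs = c("Xiao-Qing-Long-Tang", "Xin-Yi-San", "Ge-Gen-Tang",
                   "Xiang-Sha-Liu-Jun-Zi-Tang", "Ephedra sinica",
                   "Zingiber officinale", "Cinnamomum cassia",
                   "Pinellia ternata")),
    list(label = "wind syndrome",
         core = "Angelica dahurica",
         herbs = c("Angelica dahurica", "Saposhnikovia divaricata",
                   "Schizonepeta tenuifolia", "Ligusticum chuanxiong",
                   "Ligusticum sinense", "Cryptotympana pustulata")),
    list(label = "phlegm syndrome",
         core = "Platycodon grandiflorum",
         herbs = c("Platycodon grandiflorum", "Fritillaria thunbergii",
                   "Prunus armeniaca", "Glycyrrhiza uralensis",
                   "Citrus reticulata")),
    list(label = "heat-toxin syndrome",
         core = "Forsythia suspensa",
         herbs = c("Forsythia suspensa", "Lonicera japonica")),
    list(label = "Qi-stagnation syndrome",
         core = "Jia-Wei-Xiao-Yao-San",
         herbs = c("Jia-Wei-Xiao-Yao-San", "Cyperus rotundus"))
  )
}

# The background repertoire stands in for the long tail of herbs used
# outside the network; a claims extract carries hundreds of distinct
# codes, so the pool is large enough that no background pair reaches the
# mining support floor.
ar_background_herbs <- function() {
  c("Poria cocos", "Atractylodes macrocephala", "Astragalus membranaceus",
    "Chrysanthemum morifolium", "Magnolia biondii", "Ophiopogon japonicus",
    "Paeonia lactiflora", "Schisandra chinensis", "Bupleurum chinense",
    "Coix lacryma-jobi", "Morus alba", "Perilla frutescens",
    sprintf("SH%03d", 13:60))
}

#' Herb type map (herbal formula vs single herb) for the AR demo herbs
#'
#' @return data.frame with `herb`, `type` (`"HF"` or `"SH"`).
#' @export
ar_herb_types <- function() {
  herbs <- c(unlist(lapply(ar_cluster_rosters(), `[[`, "herbs")),
             ar_background_herbs())
  hf <- c("Xin-Yi-Qing-Fei-Tang", "Cang-Er-San", "Xiao-Qing-Long-Tang",
          "Xin-Yi-San", "Ge-Gen-Tang", "Xiang-Sha-Liu-Jun-Zi-Tang",
          "Jia-Wei-Xiao-Yao-San")
  data.frame(herb = herbs, type = ifelse(herbs %in% hf, "HF", "SH"),
             stringsAsFactors = FALSE)
}

#' Default planted-network spec for the AR demo
#'
#' Six communities over 31 herbs: two formula-centred clusters, two
#' single-herb clusters and two isolated dyads, plus a 60-herb background
#' pool standing in for the long tail of rarely used herbs. Cluster
#' weights equal the intended core prevalences (25.5 percent for the top
#' formula, 22.9 for the second, 16.2 for the leading single herb); with
#' co-draw weight 0.8 against background weight 0.05 the partition is
#' recoverable by the downstream clustering.
#'
#' @param n_prescriptions number of transactions (default 20,000).
#' @param seed integer seed.
#' @param co_draw within-cluster co-draw weight (default 0.8).
#' @param background_mass background filler weight (default 0.05); see
#'   [planted_network_spec()].
#' @param cluster_mixing cross-cluster filler probability (default 0).
#' @return a [planted_network_spec()].
#' @export
ar_network_spec <- function(n_prescriptions = 20000, seed = 1L,
                            co_draw = 0.8, background_mass = 0.05,
                            cluster_mixing = 0) {
  clusters <- lapply(ar_cluster_rosters(), function(cl) {
    list(herbs = cl$herbs, core = cl$core, co_draw = co_draw)
  })
  planted_network_spec(
    clusters = clusters,
    background_herbs = ar_background_herbs(),
    n_prescriptions = n_prescriptions,
    cluster_weights = c(0.255, 0.229, 0.162, 0.155, 0.100, 0.099),
    background_mass = background_mass,
    cluster_mixing = cluster_mixing,
    seed = seed)
}

#' Cluster labels of the planted AR communities
#'
#' @return character vector of syndrome labels, one per planted cluster.
#' @export
ar_cluster_labels <- function() {
  vapply(ar_cluster_rosters(), `[[`, "", "label")
}

#' Synthetic pharmacology fixture for the AR demo
#'
#' Builds the ingredient/target/pathway side of the analysis with planted
#' coverage structure: a protein universe split into an herb-biased pool,
#' a comparator-drug (western medicine) pool, a shared set of
#' inflammation proteins and an unrelated background pool. Herb
#' ingredients target the herb pool, 39 comparator drugs in four classes
#' target the drug pool, and the pathway collection plants 140 herb-side
#' pathways (19 of them immune) and 55 drug-side pathways (8 immune)
#' plus background pathways overlapping neither, so the coverage counts
#' recovered by the overrepresentation analysis are known by
#' construction.
#'
#' @param seed integer seed.
#' @return list with `ingredient_db` (ingredients + targets), `wm`
#'   (`drugs` data.frame and `targets` map), `collection`
#'   (a `pathway_collection`), `immune_proteins` (the shared
#'   inflammation symbols) and `herbs` (the 31 network herbs).
#' @export
ar_pharm_fixture <- function(seed = 1L) {
  immune <- c("FOS", "TNFA", "IL-6", "IL-8", "IL-13", "MMP9", "MIF",
              "COLI", "LOX5", "IFNG", "IL-4", "IL-10", "TLR4", "NFKB1",
              "STAT3", "CXCL10", "CCL2", "ICAM1")
  chm_only <- sprintf("CP%04d", seq_len(382))
  wm_only <- sprintf("WP%04d", seq_len(132))
  bg_only <- sprintf("BP%04d", seq_len(250))
  chm_pool <- c(chm_only, immune)              # 400 proteins
  wm_pool <- c(wm_only, immune)                # 150 proteins
  universe <- c(chm_only, wm_only, bg_only, immune)

  herbs <- unlist(lapply(ar_cluster_rosters(), `[[`, "herbs"))
  db <- generate_ingredient_db(ingredient_db_spec(
    herbs = herbs, proteins = chm_pool,
    seed = derive_seed(seed, "chm-db")))

  # 39 comparator drugs across the four guideline classes
  drugs <- data.frame(
    drug = sprintf("WM%02d", seq_len(39)),
    category = rep(c("sympathomimetics", "antihistamines", "LRA",
                     "glucocorticoids"), c(14, 13, 4, 8)),
    stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, "wm-targets"), {
    k <- sample(5:25, nrow(drugs), replace = TRUE)
    tg <- lapply(k, function(ki) wm_pool[sample.int(length(wm_pool), ki)])
    wm_targets <- data.frame(agent = rep(drugs$drug, lengths(tg)),
                             protein = unlist(tg), stringsAsFactors = FALSE)
  })

  imm_cats <- c("Immune System/Innate Immune System",
                "Immune System/Adaptive Immune System",
                "Immune System/Cytokine Signaling in Immune system")
  other_cats <- c("Signal Transduction/GPCR signaling",
                  "Metabolism/Biological oxidations",
                  "Gene expression/Transcription",
                  "Cell Cycle/Mitotic",
                  "Hemostasis/Platelet activation")
  chm_cats <- c(rep(imm_cats, c(8, 7, 4)),            # 19 immune
                rep(other_cats, length.out = 121))
  wm_cats <- c(rep(imm_cats, c(1, 1, 6)),             # 8 immune
               rep(other_cats, length.out = 47))
  coll <- combine_collections(
    generate_pathways(140, c(10, 40), universe, chm_cats,
                      seed = derive_seed(seed, "pw-chm"),
                      member_pool = chm_only, prefix = "CHMPW"),
    generate_pathways(55, c(10, 40), universe, wm_cats,
                      seed = derive_seed(seed, "pw-wm"),
                      member_pool = wm_only, prefix = "WMPW"),
    generate_pathways(105, c(10, 40), universe,
                      c(other_cats, "Neuronal System/Transmission"),
                      seed = derive_seed(seed, "pw-bg"),
                      member_pool = bg_only, prefix = "BGPW"))

  list(ingredient_db = db,
       wm = list(drugs = drugs, targets = wm_targets),
       collection = coll, immune_proteins = immune, herbs = herbs)
}
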