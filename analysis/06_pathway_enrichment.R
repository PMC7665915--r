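#!/usr/bin/env Rscript
# Hypergeometric overrepresentation of the herb-network and comparator
# target sets against the pathway collection, with BH-FDR coverage and
# the immune-category coverage comparison.
source("analysis/00_common.R")

coll <- read_gmt(out("pathways.gmt"),
                 universe = ar_pharm_fixture(seed = cfg$seed)$collection$universe)
ct <- read_csv_c(out("clusters.csv"))
kept <- read_csv_c(out("ingredients_filtered.csv"))
tg <- read_csv_c(out("ingredient_targets.csv"))
wm_drugs <- read_csv_c(out("wm_drugs.csv"))
wm_tg <- read_csv_c(out("wm_targets.csv"))

memb <- stats::setNames(ct$cluster, ct$herb)
chm_targets <- sort(unique(unlist(
  suppressWarnings(cluster_targets(memb, kept, tg)))))
wm_targets <- sort(unique(wm_tg$protein))

res_chm <- run_ora(chm_targets, coll, alpha = cfg$alpha,
                   method = cfg$correction)
res_wm <- run_ora(wm_targets, coll, alpha = cfg$alpha,
                  method = cfg$correction)
write_csv_c(res_chm, out("enrichment_chm.csv"), meta)
write_csv_c(res_wm, out("enrichment_wm.csv"), meta)
note("covered pathways (q <= ", cfg$alpha, "): herb network ",
     sum(res_chm$covered), ", comparator drugs ", sum(res_wm$covered))

cov <- compare_coverage(list(chm = res_chm, wm = res_wm),
                        category_filter = "Immune System")
counts_df <- data.frame(category = rownames(cov$counts), cov$counts,
                        row.names = NULL, check.names = FALSE)
write_csv_c(counts_df, out("coverage_immune.csv"), meta)
note("immune-system coverage by subcategory:")
for (i in seq_len(nrow(counts_df))) {
  note("  ", counts_df$category[i], ": herb network ", counts_df$chm[i],
       ", drugs ", counts_df$wm[i])
}
note("totals: herb network ", sum(cov$counts[, "chm"]),
     " immune pathways, drugs ", sum(cov$counts[, "wm"]))
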