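#!/usr/bin/env Rscript
# Ingredient screening (OB > 0.30, DL > 0.18, organic only) and
# aggregation of target proteins per network cluster, compared against
# the four comparator-drug classes on the shared inflammation proteins.
source("analysis/00_common.R")

ing <- read_csv_c(out("ingredients.csv"))
ing$inorganic <- as.logical(ing$inorganic)
tg <- read_csv_c(out("ingredient_targets.csv"))
ct <- read_csv_c(out("clusters.csv"))
wm_drugs <- read_csv_c(out("wm_drugs.csv"))
wm_tg <- read_csv_c(out("wm_targets.csv"))

kept <- filter_ingredients(ing, cfg$ob_min, cfg$dl_min,
                           ob_units = cfg$ob_units)
write_csv_c(kept, out("ingredients_filtered.csv"), meta)
note(nrow(kept), " of ", nrow(ing), " ingredients pass the ",
     "bioavailability/drug-likeness screen (",
     round(100 * nrow(kept) / nrow(ing), 1), "%)")

memb <- stats::setNames(ct$cluster, ct$herb)
cl_sets <- suppressWarnings(cluster_targets(memb, kept, tg))
wm_sets <- comparator_targets(wm_drugs, wm_tg)
note("cluster target-set sizes: ",
     paste(names(cl_sets), vapply(cl_sets, length, 0L),
           sep = "=", collapse = ", "))

fx_immune <- ar_pharm_fixture(seed = cfg$seed)$immune_proteins
ov <- overlap_table(cl_sets, wm_sets, fx_immune)
write_csv_c(ov, out("overlap_immune.csv"), meta)
counts <- attr(ov, "counts")
note("clusters sharing immune proteins with all four drug classes: ",
     sum(apply(counts > 0, 1, all)))
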