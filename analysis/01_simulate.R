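#!/usr/bin/env Rscript
# Simulate the study inputs: a user/nonuser cohort whose marginals follow
# the published baseline table, 20,000 prescription transactions with six
# planted herb communities, and the ingredient/target/pathway fixture.
source("analysis/00_common.R")

note("cohort: published marginals, full study size")
cohort <- generate_cohort(ar_cohort_spec(seed = cfg$seed))
write_csv_c(cohort, out("cohort.csv"), meta)
note("  ", nrow(cohort), " patients (", sum(cohort$chm_user), " CHM users)")

note("prescriptions: planted six-community structure")
px <- generate_prescriptions(
  ar_network_spec(n_prescriptions = cfg$n_prescriptions, seed = cfg$seed))
write_prescriptions(px, out("prescriptions.csv"), comments = meta)
note("  ", nrow(px), " prescriptions, mean ",
     round(mean_prescription_size(px), 2), " herbs each")

note("pharmacology fixture: ingredients, targets, comparator drugs, pathways")
fx <- ar_pharm_fixture(seed = cfg$seed)
write_csv_c(fx$ingredient_db$ingredients, out("ingredients.csv"), meta)
write_csv_c(fx$ingredient_db$targets, out("ingredient_targets.csv"), meta)
write_csv_c(fx$wm$drugs, out("wm_drugs.csv"), meta)
write_csv_c(fx$wm$targets, out("wm_targets.csv"), meta)
write_gmt(fx$collection, out("pathways.gmt"))
note("  ", nrow(fx$ingredient_db$ingredients), " ingredients across ",
     length(fx$herbs), " herbs; ", length(fx$collection$pathways),
     " pathways")
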