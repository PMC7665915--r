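#!/usr/bin/env Rscript
# Association-rule mining of herb pairs: support/confidence/lift for every
# co-prescribed pair, the top-100 combinations, and the single-herb
# prevalence ranking by herb type.
source("analysis/00_common.R")

px <- read_prescriptions(out("prescriptions.csv"))
note(nrow(px), " prescriptions, mean size ",
     round(mean_prescription_size(px), 2))

rules <- mine_pair_rules(px, cfg$min_support, cfg$min_confidence,
                         cfg$min_lift)
top <- top_rules(rules, cfg$top_n)
write_csv_c(rules, out("rules_all.csv"), meta)
write_csv_c(top, out("rules_top100.csv"), meta)
note(nrow(rules), " directed rules pass the thresholds (support >= ",
     cfg$min_support, "%, confidence >= ", cfg$min_confidence,
     "%, lift >= ", cfg$min_lift, "); ", nrow(top), " pairs kept")
note("strongest combination: ", top$antecedent[1], " with ",
     top$consequent[1], " (support ", round(top$support[1], 3),
     "%, confidence ", round(top$confidence[1], 3), "%, lift ",
     round(top$lift[1], 3), ")")

prev <- prevalence_ranking(px, ar_herb_types())
write_csv_c(prev, out("prevalence.csv"), meta)
hf <- prev[prev$type == "HF", ]
sh <- prev[prev$type == "SH", ]
note("most prescribed formula: ", hf$herb[1], " (", round(hf$prevalence[1],
     1), "% of prescriptions); most prescribed single herb: ", sh$herb[1],
     " (", round(sh$prevalence[1], 1), "%)")
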