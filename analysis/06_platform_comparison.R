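#!/usr/bin/env Rscript
# Stage 6: classifier degradation across array platform generations.
#
# 100 repeated 70/30 stratified splits per platform probe subset (EPICv2 23,
# EPICv1 12, Methyl450K 5, Methyl27K 2), shared split seeds across platforms,
# Welch t comparisons of the per-iteration metric distributions.

source("analysis/00_config.R")

coh <- generate_cohort(study_config())
out <- platform_degradation(coh$dataset, coh$annotation,
                            n_iter = N_ITERATIONS, root_seed = ROOT_SEED)

summary_rows <- do.call(rbind, lapply(names(out$evaluations), function(pf) {
  ev <- out$evaluations[[pf]]
  data.frame(platform = pf,
             n_probes = length(select_locus_probes(coh$annotation, pf)),
             accuracy_mean = unname(ev$summary$accuracy["mean"]),
             accuracy_sd = unname(ev$summary$accuracy["sd"]),
             type1_mean = unname(ev$summary$type1["mean"]),
             type2_mean = unname(ev$summary$type2["mean"]))
}))
message("per-platform means over ", N_ITERATIONS, " splits:")
print(summary_rows, digits = 4)

per_iter <- do.call(rbind, lapply(names(out$evaluations), function(pf)
  cbind(platform = pf, out$evaluations[[pf]]$metrics)))
write_tsv(per_iter, "platform_iteration_metrics.tsv")
write_tsv(summary_rows, "platform_summary.tsv")
write_tsv(out$comparison, "platform_comparisons.tsv")
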