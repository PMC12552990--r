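#!/usr/bin/env Rscript
# Stage 7: frozen-model application to an independent cohort.
#
# Loads the plain-text model frozen in stage 5 and applies it, unchanged, to
# a 2,458-sample independent cohort carrying 4 hidden expansion carriers.
# Labels exist only in the generator's ground truth, mimicking a cohort
# screened without prior repeat-length data.

source("analysis/00_config.R")

model_path <- file.path(results_dir, "predictor_epicv2.model")
if (!file.exists(model_path))
  stop("run analysis/05_locus_classifier.R first (missing ", model_path, ")")
model <- read_predictor_model(model_path)

ind_cfg <- implant_table1_profile(
  sim_config(n_samples = 2458L, n_background_probes = 0L,
             seed = ROOT_SEED + 1L))
ind <- generate_independent_cohort(ind_cfg, n_hidden_carriers = 4L)

out <- apply_model(model, ind$dataset)
message("predicted carriers: ", out$n_predicted, " of ", nrow(ind$dataset$m),
        sprintf(" (prevalence %.2f%%)", 100 * out$prevalence))

truth_ids <- names(which(ind$truth$carrier == "carrier"))
message("ground-truth carriers recovered: ",
        length(intersect(out$predicted_carriers, truth_ids)), " of ",
        length(truth_ids),
        "; false calls: ", length(setdiff(out$predicted_carriers, truth_ids)))

calls <- out$predictions[order(-out$predictions$probability), ]
write_tsv(utils::head(calls, 20), "validation_top_calls.tsv")
write_tsv(data.frame(sample_id = out$predicted_carriers,
                     probability = out$predictions$probability[
                       match(out$predicted_carriers,
                             out$predictions$sample_id)],
                     in_ground_truth = out$predicted_carriers %in% truth_ids),
          "validation_predicted_carriers.tsv")
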