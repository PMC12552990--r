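#!/usr/bin/env Rscript
# Stage 5: locus-restricted carrier classifier.
#
# Restricts to the 23 EPICv2 probes in the C9orf72 gene +/- 1 kb, shows the
# PCA separation of carriers, then trains a single 70/30-split LASSO model
# (10-fold CV penalty) and freezes it to plain text for the validation stage.

source("analysis/00_config.R")

coh <- generate_cohort(study_config())
probes <- select_locus_probes(coh$annotation, platform = "epicv2")
message(length(probes), " locus probes on EPICv2")

pc <- locus_pca(coh$dataset, probes)
pc_out <- data.frame(sample_id = rownames(pc), pc,
                     carrier = coh$dataset$carrier)
write_tsv(pc_out, "locus_pca_scores.tsv")
sep <- abs(mean(pc[coh$dataset$carrier == "carrier", "PC1"]) -
           mean(pc[coh$dataset$carrier == "non_carrier", "PC1"]))
message(sprintf("PC1 carrier/non-carrier mean separation: %.2f", sep))

sp <- split_train_test(coh$dataset, train_fraction = 0.7, seed = ROOT_SEED)
message("train ", nrow(sp$train$m), " (", sum(sp$train$carrier == "carrier"),
        " carriers) / test ", nrow(sp$test$m), " (",
        sum(sp$test$carrier == "carrier"), " carriers)")

model <- train_lasso(sp$train, probes, cv_folds = 10L, seed = ROOT_SEED)
print(model)
nz <- model$coefficients[model$coefficients != 0]
message("probes selected: ", paste(names(nz), collapse = ", "))

pred <- predict_carriers(model, sp$test)
met <- split_metrics(sp$test$carrier, pred$label)
message(sprintf("single-split test accuracy %.3f (type I %.3f, type II %.3f)",
                met$accuracy, met$type1, met$type2))

write_predictor_model(model, file.path(results_dir, "predictor_epicv2.model"))
message("  wrote results/predictor_epicv2.model")
write_tsv(data.frame(metric = c("accuracy", "type1", "type2", "tp", "fp",
                                "tn", "fn"),
                     value = unlist(met)),
          "single_split_metrics.tsv")
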