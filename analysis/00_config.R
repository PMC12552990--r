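# Shared study configuration for the analysis scripts.
#
# One cohort definition is used throughout: 277 whole-blood samples with 27
# pathogenic C9orf72 repeat-expansion carriers, the 23-probe locus manifest,
# the eight implanted hypermethylated probes (effect profile 4.0 down to 1.5
# M units), and 20,000 genome-wide null probes with covariate and batch
# structure. Every script regenerates it deterministically from ROOT_SEED
# instead of passing multi-megabyte matrices around.

library(c9methpred)

ROOT_SEED <- 1L
N_BACKGROUND <- 20000L
N_PERMUTATIONS <- 100L
N_ITERATIONS <- 100L

study_config <- function(seed = ROOT_SEED, n_background = N_BACKGROUND)
  implant_table1_profile(
    sim_config(n_samples = 277L, n_carriers = 27L,
               n_background_probes = n_background, seed = seed))

results_dir <- file.path("results")
scratch_dir <- file.path("scratch")
dir.create(results_dir, showWarnings = FALSE)
dir.create(scratch_dir, showWarnings = FALSE)

write_tsv <- function(df, name, dir = results_dir) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
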