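#!/usr/bin/env Rscript
# Desk-scale replication suite: controller-gain grid search plus the three
# ablation suites on the shared synthetic dataset. Budgets are reduced so
# the whole suite runs in well under 30 minutes on one CPU: grid cells rank
# configurations with a short 6-epoch budget over the kp x ki plane (target
# 0.5, max iterations 1); ablation rows use the full 40-epoch desk protocol.
# Usage: Rscript scripts/paper_suite.R [--seed <int>] [--out <dir>]

suppressPackageStartupMessages(library(picnet))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "results/paper_suite")
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}
dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

ds <- generate_nodule_images(synthetic_preset("balanced", n_images = 400,
                                              seed = opt$seed + 100L))
sp <- split_dataset(ds, seed = opt$seed)

grid <- default_gain_grid()
grid$target_intensity <- 0.5
grid$max_iterations <- 1L
gs <- run_grid_search(sp, model_config("manual_before", input_size = 64,
                                       seed = opt$seed),
                      train_config(epochs = 6, seed = opt$seed), grid)
write.csv(gs$table, file.path(opt$out, "grid.csv"), row.names = FALSE)
jsonlite::write_json(list(winner = as.list(gs$winner),
                          test_metrics = gs$test_metrics, log = gs$log),
                     file.path(opt$out, "grid_winner.json"),
                     auto_unbox = TRUE, digits = NA)
cat("grid winner:", unlist(gs$winner), "\n")

tc <- train_config(epochs = 40, seed = opt$seed)
for (suite in c("depth_no_pic", "pic_placement", "gain_regimes")) {
  tab <- run_ablation(suite, sp, tc, input_size = 64, seed = opt$seed)
  write.csv(tab, file.path(opt$out, paste0(suite, ".csv")), row.names = FALSE)
  cat(suite, "done:", nrow(tab), "configurations\n")
}
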