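# Shared setup for the numbered analysis scripts. Each script is a thin
# narrative driver over the methsuite package: it loads (or extends) the
# cached pipeline run, reports what it found, and writes its tables under
# results/. Set METHSUITE_SEED to change the master seed (default 1).

suppressMessages({
  library(methsuite)
  library(data.table)
})

SEED <- as.integer(Sys.getenv("METHSUITE_SEED", "1"))
RESULTS <- "results"
CACHE <- file.path(RESULTS, sprintf("run_cache_seed%d.rds", SEED))
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

# load the cached run if its stages suffice, otherwise compute and cache
get_run <- function(stages) {
  if (file.exists(CACHE)) {
    run <- readRDS(CACHE)
    if (all(stages %in% run$stages_done)) return(run)
  }
  run <- run_pipeline(default_config(SEED), stages = stages)
  run$stages_done <- stages
  saveRDS(run, CACHE)
  run
}

put_tsv <- function(x, name) {
  path <- file.path(RESULTS, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
}
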