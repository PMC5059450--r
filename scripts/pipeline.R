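#!/usr/bin/env Rscript
# Thin command-line wrapper over thermodiv::runPipeline().
# Usage: Rscript scripts/pipeline.R <config.yaml>
# Exit codes: 0 success, 2 configuration error, 3 stage failure.

suppressPackageStartupMessages(library(thermodiv))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1L) {
  message("usage: Rscript scripts/pipeline.R <config.yaml>")
  quit(status = 2L)
}

cfg <- tryCatch(yaml::read_yaml(args[1L]), error = function(e) {
  message("cannot read config: ", conditionMessage(e))
  quit(status = 2L)
})
ok <- tryCatch({
  validatePipelineConfig(cfg)
  TRUE
}, error = function(e) {
  message("invalid config: ", conditionMessage(e))
  FALSE
})
if (!ok) quit(status = 2L)

res <- tryCatch({
  runPipeline(cfg)
  TRUE
}, error = function(e) {
  message(conditionMessage(e))
  FALSE
})
quit(status = if (res) 0L else 3L)
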