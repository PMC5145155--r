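#!/usr/bin/env Rscript
# Thin shell wrapper over daneuron::run_protocol():
#   Rscript scripts/run_protocol.R <config.yaml> [<out_dir>] [--seed <int>]
suppressPackageStartupMessages(library(daneuron))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  stop("usage: Rscript scripts/run_protocol.R <config.yaml> [<out_dir>] ",
       "[--seed <int>]")
}
seed <- NULL
i <- which(args == "--seed")
if (length(i)) {
  seed <- as.integer(args[i + 1])
  args <- args[-c(i, i + 1)]
}
config <- args[1]
out_dir <- if (length(args) >= 2) args[2] else
  file.path("out", tools::file_path_sans_ext(basename(config)))
run_protocol(config, out_dir, seed = seed)
cat("results written to", out_dir, "\n")
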