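#!/usr/bin/env Rscript
# Thin command-line wrapper over rheomicro::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R [--config <yaml|json>] --out <dir>
#                [--seed <int>] [--subjects <int>] [--quiet]

suppressPackageStartupMessages(library(rheomicro))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
out <- get_arg("--out")
if (is.null(out)) stop("--out <dir> is required")
config <- get_arg("--config")
seed <- get_arg("--seed")
subjects <- get_arg("--subjects")

run_pipeline(config = config, out_dir = out,
             seed = if (!is.null(seed)) as.integer(seed),
             n_subjects = if (!is.null(subjects)) as.integer(subjects),
             quiet = "--quiet" %in% args)
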