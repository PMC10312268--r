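#!/usr/bin/env Rscript

## Thin command-line wrapper over usemnet::run_full().
##
## Usage:
##   Rscript scripts/run_pipeline.R [--config file.yaml] [--out dir]
##       [--seed int] [--no-subgroups] [--no-simulate --input dir]
##
## The config file is a flat YAML map of run_full() configuration keys
## (see ?validate_config); command-line flags override it.

suppressPackageStartupMessages(library(usemnet))

args <- commandArgs(trailingOnly = TRUE)
getopt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1L]
}
has <- function(flag) flag %in% args

cfg <- list()
cfg_file <- getopt("--config")
if (!is.null(cfg_file)) cfg <- yaml::read_yaml(cfg_file)
if (!is.null(getopt("--out"))) cfg$output_dir <- getopt("--out")
if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
if (has("--no-subgroups")) cfg$run_subgroups <- FALSE
if (has("--no-simulate")) {
  cfg$simulate <- FALSE
  cfg$input_dir <- getopt("--input")
}

res <- run_full(cfg)
cat(res$report, sep = "\n")
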