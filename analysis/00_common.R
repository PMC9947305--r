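# Shared plumbing for the numbered analysis drivers: argument handling and
# the results directory. Each driver is runnable on its own from the
# repository root, e.g.  Rscript analysis/01_simulate.R --seed 1
suppressPackageStartupMessages(library(beetol))

args <- commandArgs(trailingOnly = TRUE)
arg_or <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
SEED <- as.integer(arg_or("--seed", "1"))
RESULTS <- arg_or("--out", "results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
GENES <- c("CYP9Q1", "CYP9Q2", "CYP9Q3")
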