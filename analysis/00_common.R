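# Shared setup sourced by every numbered driver: configuration, output
# directory, and a tiny logger. Run the drivers from the repository root.
library(chmnet)

cfg <- validate_config(
  if (file.exists("analysis/config.yaml")) read_config("analysis/config.yaml")
  else list())
res_dir <- "results"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)
meta <- paste0("chmnet ", as.character(utils::packageVersion("chmnet")),
               " seed=", cfg$seed)
out <- function(f) file.path(res_dir, f)
note <- function(...) message("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
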