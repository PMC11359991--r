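# Shared helpers: deterministic generator configurations used across tests.

noise_free_presets <- function(seed = 1L) {
  cfgs <- tissue_presets(seed = seed)
  for (nm in names(cfgs)) {
    cfgs[[nm]]$noise_sd <- 0
    cfgs[[nm]]$volume_rel_uncertainty <- 0
    cfgs[[nm]]$initial_weight_cv <- 0
  }
  cfgs
}

# decimal places of a printed number ("5.435" -> 3, "27.5" -> 1, "42" -> 0)
printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub(".*\\.", "", s)), 0L)
}
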