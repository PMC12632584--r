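# the Monte-Carlo recovery runs are shared across acceptance checks
# (coefficient recovery and CI coverage read the same replicates)
recovery_cache <- local({
  cache <- list()
  function(preset, replicates, seed, cells = NULL) {
    key <- paste(preset, replicates, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cache[[key]] <<- recovery_study(preset, cells = cells,
                                      replicates = replicates, seed = seed)
    }
    cache[[key]]
  }
})
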