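# The default-condition benchmark (10 subgroup cells x 200 spectra) is
# expensive, so it is run once and shared by the tests that consume it.
default_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_experiment(pipeline_config(seed = 1),
                               file.path(tempdir(), "tdh_default_bench"))
    cache
  }
})
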