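# One full-scale protocol run (default synthetic cohort, master seed 1,
# planted rules as the clinical prior), shared by the end-to-end tests.
# Memoised so the expensive computation happens once per test run.
protocol_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(seed = 1)
      flt <- apply_filters(co$pairs, cohort_schema(co$pairs))
      out_dir <- file.path(tempdir(), "fuzznet-protocol-fixture")
      t0 <- Sys.time()
      res <- run_full_protocol(flt$pairs, flt$schema,
                               train_config(seed = 1),
                               init_ruleset = co$truth, out_dir = out_dir)
      elapsed <- as.numeric(Sys.time() - t0, units = "secs")
      cache <<- list(cohort = co, filtered = flt, result = res,
                     out_dir = out_dir, elapsed = elapsed)
    }
    cache
  }
})
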