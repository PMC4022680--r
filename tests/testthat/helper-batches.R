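# Shared simulation batches for the acceptance tests, computed once per test
# run. 100 replicates per condition; the full transfer grid (10-100% in steps
# of 10). Group of 10: all nine calibration ratios; group of 20: the five
# ratios below 1.5 plus, separately, ratio 0.11 over the 20-100% transfer
# range.

.batch_cache <- new.env(parent = emptyenv())

acceptance_batch <- function(which = c("n10_full", "n20_low")) {
  which <- match.arg(which)
  if (!is.null(.batch_cache[[which]])) return(.batch_cache[[which]])
  grid <- switch(which,
    n10_full = standard_conditions(n = 10),
    n20_low = standard_conditions(n = 20,
                                  ratio = c(1, 0.67, 0.43, 0.25, 0.11)))
  .batch_cache[[which]] <- run_batch(grid, reps = 100, base_seed = 20140515)
  .batch_cache[[which]]
}
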