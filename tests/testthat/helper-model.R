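# A small trained model shared by the model/pipeline tests: 4 training
# phantoms, 2 held out, built once per test run.
.ssn_cache <- new.env(parent = emptyenv())

cached_phantom_fixture <- function() {
  if (!is.null(.ssn_cache$fixture)) return(.ssn_cache$fixture)
  coh <- generate_cohort(6, seed = 31)
  cases <- lapply(1:4, function(i) {
    b <- coh$bundles[[i]]
    ann <- suppressWarnings(
      sparse_annotations(b$truth, per_class = 100, seed = 300 + i))
    list(volume = b$volume, annotations = ann,
         nodule_id = coh$manifest$id[i])
  })
  model <- suppressWarnings(train_model(cases, k = 100, seed = 3))
  .ssn_cache$fixture <- list(cohort = coh, model = model)
  .ssn_cache$fixture
}
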