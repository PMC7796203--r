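# The full-scale pipeline run (9 classes x 20 train + 20 test trials of
# 1 s at 2 kHz) takes several minutes; it is computed once per test session
# and shared by every test that needs study-scale artifacts.
.semgpe_test_cache <- new.env(parent = emptyenv())

full_scale_run <- function() {
  if (!is.null(.semgpe_test_cache$run)) return(.semgpe_test_cache$run)
  dir <- file.path(tempdir(), "semgpe-full-scale")
  cfg <- pipeline_config()
  res <- semg_run_all(dir, cfg, seed = 2026L)
  .semgpe_test_cache$run <- list(dir = dir, cfg = cfg, res = res)
  .semgpe_test_cache$run
}

# A reduced configuration for structural / reproducibility tests: complete
# pipeline, small problem.
small_config <- function(trials_train = 3L, trials_test = 2L, seed = 1L) {
  pipeline_config(
    trials_train = trials_train, trials_test = trials_test,
    duration = 0.25,
    train = train_config(layer_sizes = c(40L, 40L), epochs_pretrain = 5L,
                         epochs_finetune = 50L, batch_size = 9L, seed = seed),
    seed = seed)
}
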