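# Desk-scale trained surrogates, built once per test run and shared across
# test files (training dominates the suite's runtime).

.desk_cache <- new.env(parent = emptyenv())

desk_cfs <- function() c(500, 1000, 2000)

get_desk_ihc <- function() {
  if (!is.null(.desk_cache$ihc)) return(.desk_cache$ihc)
  corpus <- speech_like_corpus(6, 1.0, SOLVE_FS, seed = 42)
  ws <- build_training_set(corpus, "ihc", desk_specs()$ihc, desk_cfs(),
                           seed = 42, max_windows = 384)
  res <- train_surrogate(desk_specs()$ihc, ws,
                         train_config(learning_rate = 1e-3, epochs = 120,
                                      batch_size = 32, seed = 7,
                                      patience = 50, lr_decay = 0.3,
                                      decay_every = 40))
  .desk_cache$ihc <- res
  res
}

get_desk_anf <- function() {
  if (!is.null(.desk_cache$anf)) return(.desk_cache$anf)
  corpus <- speech_like_corpus(4, 0.6, SOLVE_FS, seed = 43)
  ws <- build_training_set(corpus, "anf", desk_specs()$anf, c(1000, 4000),
                           fiber = fiber_preset("hsr"), seed = 43,
                           max_windows = 192)
  res <- train_surrogate(desk_specs()$anf, ws,
                         train_config(learning_rate = 2e-3, epochs = 60,
                                      batch_size = 32, seed = 11,
                                      patience = 20))
  .desk_cache$anf <- res
  res
}
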