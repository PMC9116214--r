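# A small corpus shared by unit tests that need trained-model mechanics but
# not the full packaged benchmark.

small_cache <- new.env(parent = emptyenv())

small_corpus <- function() {
  if (is.null(small_cache$corpus)) {
    small_cache$corpus <- simulate_training_corpus(
      n_natives = 12L, n_decoys_per_native = 10L, seed = 7L,
      n_residues = c(6L, 12L), n_ligand_atoms = c(6L, 14L)
    )
  }
  small_cache$corpus
}

small_model <- function() {
  if (is.null(small_cache$model)) {
    train <- suppressMessages(filter_training_poses(small_corpus()))
    small_cache$model <- train_sfct(train,
      sfct_hyperparams(n_boost_rounds = 3L, trees_per_forest = 20L, seed = 5L))
  }
  small_cache$model
}
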