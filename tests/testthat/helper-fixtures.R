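# Small-scale fixtures built in code; all sizes chosen for fast tests.

# A desk-scale cohort with short trials (structure identical to the default).
small_cohort <- function(seed = 1L, len = c(120L, 240L), effects = list(
                           force_z = c(temporal = 3),
                           force_x = c(mental = 2, stress = 2))) {
  generate_cohort(generator_config(trial_length_range = len,
                                   force_rate = 50, effect_sizes = effects,
                                   seed = seed))
}

# Equal-length random series for classifier tests: a mean shift `shift` on
# channel 1 separates the classes.
shifted_series <- function(n_per_class, tt, n_chan = 2L, shift = 3,
                           seed = 1L) {
  set.seed(seed)
  mk <- function(s) {
    m <- matrix(stats::rnorm(tt * n_chan), tt, n_chan)
    m[, 1] <- m[, 1] + s
    m
  }
  list(series = c(lapply(seq_len(n_per_class), function(i) mk(0)),
                  lapply(seq_len(n_per_class), function(i) mk(shift))),
       labels = rep(0:1, each = n_per_class))
}

# Wrap plain matrices as assembled_series so loocv/normalization apply.
as_series <- function(m, id, orig = nrow(m)) {
  structure(list(trial_id = id, values = m,
                 channel_names = colnames(m), original_length = orig),
            class = "assembled_series")
}

# Oracle stub classifier: predicts the true label of the held-out trial.
oracle_trainer <- function(truth) {
  function(config, train_series, train_labels) list(truth = truth)
}
oracle_predictor <- function(model, series) model$truth[[series$trial_id]]

# An eval-mode identity convolution block: kernel 1, BN frozen to identity.
identity_block <- function(n_chan) {
  list(W = array(diag(n_chan), c(1L, n_chan, n_chan)),
       b = numeric(n_chan), gamma = rep(1, n_chan), beta = numeric(n_chan),
       mean = numeric(n_chan), var = rep(1, n_chan))
}
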