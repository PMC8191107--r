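# Shared fixtures: tiny model configurations and fabricated segment stacks
# so model-level tests run in milliseconds.

tiny_model_config <- function(n_classes = 3, window_size = 20,
                              d_model = 8, n_heads = 2) {
  model_config(conv_layers = list(list(3L, 5L, 2L), list(4L, 3L, 2L)),
               cnn_feature_dim = 6, d_model = d_model, n_encoder_layers = 2,
               n_heads = n_heads, ffn_hidden = 12, n_classes = n_classes,
               classifier_hidden = 5, window_size = window_size)
}

fake_stack <- function(record_id, n_win, label, window = 20, sd = 0.5,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(list(record_id = record_id,
                 segments = array(rnorm(n_win * 12 * window, sd = sd),
                                  dim = c(n_win, 12, window)),
                 label = as.integer(label), fs = 500),
            class = "segment_stack")
}

# Small cached clean record (6 s, class normal) reused across tests.
fixture_record <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_records = 1, n_classes = 1,
                             duration_range = c(6, 6), seed = 400)
      cache <<- generate_record(spec, "normal", record_id = "fix1", seed = 400)
    }
    cache
  }
})
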