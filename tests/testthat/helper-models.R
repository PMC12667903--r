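# Trained-model fixture, built once per test session and shared between the
# learned-invariance, pipeline and node-map tests. Study conditions: 30
# synthetic families x 8 training members (2 more held out per family),
# chain length 80, coordinate noise 0.3 A, 100 epochs, fixed seeds; one
# encoder trained with synCP augmentation (CP-invariant) and one without
# (CP-sensitive baseline).

.fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  fams <- lapply(1:30, function(j)
    make_synthetic_family(10, 80, 0.3, seed = 1000 + j,
                          label = sprintf("a.%d.1.1", j)))
  train_traces <- unlist(lapply(fams, function(f) f[1:8]), recursive = FALSE)
  heldout <- unlist(lapply(fams, function(f) f[9:10]), recursive = FALSE)
  m_aug <- train(train_traces,
                 model_config(epochs = 100, seed = 7, syncp_augment = TRUE),
                 val_traces = heldout)
  m_base <- train(train_traces,
                  model_config(epochs = 100, seed = 7, syncp_augment = FALSE),
                  val_traces = heldout)
  .fixture_env$fx <- list(m_aug = m_aug, m_base = m_base,
                          heldout = heldout)
  .fixture_env$fx
}

# held-out cosine between each structure and random synCPs of itself
syncp_selfcos <- function(model, traces, ks_per_trace = 5, seed = 42) {
  set.seed(seed)
  unlist(lapply(traces, function(tr) {
    g <- build_graph(tr)
    z <- encode(g, model)
    ks <- sample(seq_len(trace_length(tr)) - 1L, ks_per_trace)
    vapply(ks, function(k)
      cosv(z, encode(cpscan:::syncp_graph(g, k), model)), 0)
  }))
}
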