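# Shared fixtures: everything is generated in code at test time.

# A micro bundle for plumbing tests (not for learning).
tiny_bundle <- function(n = 10, C = 4, L = 32, label_type = "gaze",
                        seed = 99) {
  set.seed(seed)
  labels <- if (label_type == "gaze") cbind(runif(n, 0, 10), runif(n, 0, 10))
            else rbinom(n, 1, 0.5)
  eeg_bundle(array(rnorm(C * L * n), c(C, L, n)),
             sprintf("CH%02d", seq_len(C)), 128, labels, label_type)
}

# A micro model configuration that exercises every architectural piece.
tiny_config <- function(variant = "model_b", head = "gaze", C = 12, L = 16,
                        K = 4, H = 5) {
  model_config(variant, C = C, L = L, K = K, H = H, n_blocks = 2,
               transformer_layers = 1, transformer_heads = 2, head = head,
               sampling_rate = 128)
}

# Parameter-tree helpers for gradient checks.
leaf_paths <- function(p, prefix = character()) {
  if (is.list(p)) {
    out <- list()
    for (nm in names(p)) out <- c(out, leaf_paths(p[[nm]], c(prefix, nm)))
    out
  } else list(prefix)
}

get_leaf <- function(p, path) {
  for (k in path) p <- p[[k]]
  p
}

set_leaf <- function(p, path, v) {
  if (length(path) == 1L) p[[path[1L]]] <- v
  else p[[path[1L]]] <- set_leaf(p[[path[1L]]], path[-1L], v)
  p
}
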