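# Small parameter sets shared across tests. Default-network oracles are
# computed at full N = 1000; property loops run at reduced N for speed.

default_params <- function(w = 0.0125, g = 0) model_params(w = w, g = g)

small_params <- function(N = 200, g = 0, w = NULL, p = 0.2, alpha = 0.2,
                         p_ext = 0.005 / N) {
  if (is.null(w))
    w <- boundary_weight(g, model_params(N = N, p = p, alpha = alpha, w = 1,
                                         g = g, p_ext = p_ext))
  model_params(N = N, p = p, alpha = alpha, w = w, g = g, p_ext = p_ext)
}

# hand-traceable 3-neuron coupling: neuron 3 inhibitory
J3_fixture <- function() {
  matrix(c(0.0, 0.2, -0.5,
           0.4, 0.0, -0.3,
           0.1, 0.6,  0.0), 3, 3, byrow = TRUE)
}
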