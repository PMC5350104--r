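# Small shared fixtures. Everything is generated in code; nothing is stored.

tiny_params <- function(seed = 3, n_in = 6, n1 = 4, n2 = 3, n_out = 2) {
  rfam_init(n_in = n_in, n1 = n1, n2 = n2, n_out = n_out, seed = seed)
}

# deterministic 7-class curve target for quick network fits
toy_class_curves <- function() {
  k <- exp(-(0:4) / 1.5)
  m <- outer(c(random = 0.3, white_triangle = 0.25, black_triangle = 0.3,
               even = 0.8, odd = 0.2, wye = 0.25, foot = 0.35), k)
  rownames(m) <- texture_classes()
  m
}

# relative difference used by gradient checks
rel_err <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))
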