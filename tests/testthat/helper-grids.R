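# Shared fixtures built in code.

# Full isotropic box {0..L}^d as an index-set list.
full_box <- function(L, d) {
  g <- expand.grid(rep(list(0:L), d))
  lapply(seq_len(nrow(g)), function(r) as.integer(g[r, ]))
}

# A single-parameter space on [0.85, 1.15] (nominal 1): its analytic uniform
# CV is 0.15/sqrt(3).
one_input_space <- function() {
  input_space(data.frame(name = "x", nominal = 1, lo = 0.85, hi = 1.15))
}

# Small evaluation table built directly from a function energy(config, seed).
make_table <- function(configs, seeds, energy_fn) {
  do.call(rbind, lapply(seq_along(configs), function(i) {
    data.frame(config_id = i, x = configs[i], seed = seeds,
               energy = vapply(seeds, function(s) energy_fn(configs[i], s),
                               numeric(1L)))
  }))
}
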