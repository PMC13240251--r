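# Shared fixture builders; everything is generated in code at test time.

# A single small group config; defaults mirror the V12 apical-leaf group.
one_group_config <- function(n = 60, stage = "V12", leaf = "apical",
                             mean = 50.6, sd = 4.3, seed = 1, ...) {
  generator_config(groups = data.frame(stage = stage, leaf_position = leaf,
                                       n = n, spad_mean = mean,
                                       spad_sd = sd),
                   seed = seed, ...)
}

# Minimal hand-built sample set on a short grid (not the full 751 bands).
tiny_samples <- function(n = 4, wl = 325:1075, seed = 99) {
  set.seed(seed)
  m <- matrix(runif(n * length(wl), 0.1, 0.6), n,
              dimnames = list(NULL, wl))
  meta <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                     stage = "V6", leaf_position = "apical",
                     variety = "ZD958", nitrogen = "N2",
                     spad = seq(45, 60, length.out = n))
  spad_samples(meta, m, wl)
}
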