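# Thin R wrappers over the counter-based uniform stream (src/rng.cpp).
# Every stochastic quantity in the synthetic cohort is derived from
# cb_unif(seed, stream, index): `stream` identifies the field, `index` the
# participant (or participant x event slot), so regenerating with a larger n
# reproduces the first participants byte-for-byte.

r_unif <- function(seed, stream, index) {
  cb_unif(seed, stream, index)
}

r_bern <- function(seed, stream, index, prob) {
  cb_unif(seed, stream, index) < prob
}

# integer uniform on the closed range [lo, hi]; lo/hi may be vectors
r_int <- function(seed, stream, index, lo, hi) {
  u <- cb_unif(seed, stream, index)
  lo + floor(u * (hi - lo + 1))
}

# Poisson by quantile inversion of a single uniform
r_pois <- function(seed, stream, index, lambda) {
  u <- cb_unif(seed, stream, index)
  stats::qpois(u, lambda)
}

# calendar date uniform on the closed interval [from, to]
r_date <- function(seed, stream, index, from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  as.Date(r_int(seed, stream, index, as.numeric(from), as.numeric(to)),
          origin = "1970-01-01")
}

# pick one element per row from a fixed choice vector
r_pick <- function(seed, stream, index, choices) {
  choices[r_int(seed, stream, index, 1L, length(choices))]
}

# event-slot index: participant i, slot j, with a fixed per-participant cap
slot_index <- function(i, j, cap) {
  (i - 1) * cap + j
}
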