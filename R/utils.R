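# Internal helpers: deterministic seed splitting, triangle keys, misc.

# Counter-based integer splitter: derive independent sub-seeds from a master
# seed so that changing one protocol knob never perturbs an unrelated RNG
# stream.  Returns seeds in [0, 2^31 - 1].
derive_seed <- function(master_seed, counter) {
  x <- (as.double(master_seed) %% 2147483647) + 1
  for (i in seq_len(counter + 1L)) {
    # Lehmer step followed by an xorshift-style fold, all in double precision
    # (exact: intermediate values stay below 2^53).
    x <- (x * 48271) %% 2147483647
    x <- (x * 69621) %% 2147483647
  }
  as.integer(x %% 2147483647)
}

# An RNG "stream" is a saved .Random.seed vector; draws swap it in and out so
# that concerns (endogenous noise, MC translocation, mesh jitter) are
# independent of each other.
rng_stream_new <- function(seed) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

with_stream <- function(state, name, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", state$rng[[name]], envir = globalenv())
  res <- fn()
  state$rng[[name]] <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(state = state, value = res)
}

# Canonical (sorted) vertex order per triangle row, vectorised.
tri_canonical <- function(tri) {
  a <- pmin(tri[, 1], tri[, 2], tri[, 3])
  c <- pmax(tri[, 1], tri[, 2], tri[, 3])
  b <- tri[, 1] + tri[, 2] + tri[, 3] - a - c
  cbind(a, b, c, deparse.level = 0)
}

# Unique double-precision key per canonical triangle (exact for < 2^17 nodes).
tri_keys <- function(tri, n_nodes) {
  (tri[, 1] - 1) * n_nodes^2 + (tri[, 2] - 1) * n_nodes + (tri[, 3] - 1)
}

# Length-weighted mean of a per-node concentration field.
weighted_mean_conc <- function(conc, d) sum(conc * d) / sum(d)

# Saturating Hill response used by the active-force laws.
hill <- function(c, c_half, n) {
  x <- (pmax(c, 0) / c_half)^n
  x / (1 + x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
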