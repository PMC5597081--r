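# Shared fixtures.  Expensive default-world fields are generated lazily and
# cached for the session so several tests can share them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a default-parameter monolayer and its full pipeline run (the acceptance
# world: 20 cells, 10 punctae/cell, fractions 60/25/15, 20% gain)
default_field <- function(seed = 1) {
  cached(paste0("field", seed), make_monolayer(monolayer_params(seed = seed)))
}

default_quant <- function(seed = 1) {
  cached(paste0("quant", seed),
         suppressMessages(quantify_field(default_field(seed)$images)))
}

# small, fast monolayer for unit tests (6 cells)
small_field <- function(seed = 1, ...) {
  make_monolayer(monolayer_params(field_shape = c(320L, 320L), n_cells = 6L,
                                  seed = seed, ...))
}

# draw a disk into a matrix (independent of the package's renderer)
fixture_disk <- function(mat, r0, c0, radius, value = 1) {
  for (i in seq_len(nrow(mat)))
    for (j in seq_len(ncol(mat)))
      if ((i - 1 - r0)^2 + (j - 1 - c0)^2 <= radius^2) mat[i, j] <- value
  mat
}
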