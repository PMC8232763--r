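# Shared fixtures: tiny volumes and phantoms built in code.

tinyImage <- function(dims = c(6, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  ImageVolume(array(runif(prod(dims), -500, 1500), dims), spacing)
}

tinyLabel <- function(dims = c(6, 8, 8), spacing = c(1, 1, 1), p = 0.3,
                      seed = 2) {
  set.seed(seed)
  LabelVolume(array(rbinom(prod(dims), 1, p), dims), spacing)
}

smallPhantomConfig <- function(seed = 1, ...) {
  PhantomConfig(shape = c(16, 32, 32), seed = seed, ...)
}

# cube mask helper: a filled axis-aligned box
cubeMask <- function(dims, zr, yr, xr, spacing = c(1, 1, 1)) {
  m <- array(0L, dims)
  m[zr, yr, xr] <- 1L
  LabelVolume(m, spacing)
}
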