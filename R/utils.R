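## Internal helpers shared across modules.

## Derive a reproducible child seed from a base seed and an index; keeps
## the result a valid 32-bit integer.
derive_seed <- function(seed, index = 0L, salt = 0L) {
  s <- (as.double(seed) * 48271 + as.double(index) * 9973 +
          as.double(salt) * 127) %% 2147483629
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Spectral radius of a square matrix.
spectral_radius <- function(M) {
  if (!length(M)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}
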