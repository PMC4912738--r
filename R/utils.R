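# Internal helpers shared across modules.

frob <- function(x) sqrt(sum(x * x))

# Run `code` under a temporary RNG state so library internals (e.g. the
# randomised SVD probe) never perturb the caller's random stream.
with_local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
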