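# Small shared helpers.

# Run code under a fixed seed, restoring the caller's RNG state afterwards
# so generators are pure functions of (seed, parameters).
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Multiplicative log-normal noise with a given coefficient of variation,
# mean 1.
lognormNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
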