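# Evaluate expr under a locally seeded default RNG (Mersenne-Twister),
# restoring the caller's generator state afterwards, so simulator output
# depends only on the supplied seed.
with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = .GlobalEnv)) stats::runif(1)
  old_seed <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  suppressWarnings(RNGkind("Mersenne-Twister", "Inversion", "Rejection"))
  set.seed(as.integer(seed))
  expr
}
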