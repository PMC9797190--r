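## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards. All stochastic operations in
## the package route through this so a single integer seed documents each
## draw.
with_seed <- function(seed, expr) {
  # force the seed before snapshotting the stream: a lazily evaluated
  # argument drawing from the global RNG must advance it, not be rewound
  seed <- as.integer(seed %% .Machine$integer.max)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-seed derivation: one master seed, one documented
## stream per (purpose, index) pair, always below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %%
               2147483647)
}
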