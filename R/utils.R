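# run expr under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

.penlm_env <- new.env(parent = emptyenv())
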