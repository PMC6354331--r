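# run expr with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
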