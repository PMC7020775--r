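# Internal helpers.

# Evaluate code under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# flip an array along one spatial axis, preserving other axes
flip_axis <- function(x, axis) {
  dm <- dim(x)
  if (is.null(dm)) return(rev(x))
  idx <- lapply(dm, seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

drop_channel <- function(x) {
  dm <- dim(x)
  if (!is.null(dm) && dm[length(dm)] == 1L)
    array(x, dim = dm[-length(dm)])
  else x
}
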