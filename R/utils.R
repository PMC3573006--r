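# Internal helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Moving-average smoother with edge padding (window in samples, made odd).
smooth_ma <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[(h + 1L):(h + length(x))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
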