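# internal helpers

# stop with a classed condition so callers can discriminate failure modes
abort_fluxred <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "fluxred_error"), ...)
}

# exact small-vector convolution (no FFT round-off); u, w are MID vectors
conv_mid <- function(u, w) {
  n <- length(u) + length(w) - 1L
  out <- numeric(n)
  for (i in seq_along(u)) {
    idx <- i:(i + length(w) - 1L)
    out[idx] <- out[idx] + u[i] * w
  }
  out
}

conv_mid_list <- function(mids) Reduce(conv_mid, mids)

# run code with a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# key for an EMU / cumomer node
emu_key <- function(met, positions) paste0(met, "#", paste(positions, collapse = ","))

`%||%` <- rlang::`%||%`
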