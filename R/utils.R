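# internal helpers: error signalling and seeded evaluation

abort_fnirseeg <- function(msg, class) {
  stop(structure(
    class = c(paste0("fnirseeg_", class), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

warn_fnirseeg <- function(msg, class) {
  warning(structure(
    class = c(paste0("fnirseeg_", class), "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All stochastic generators in the package route through this, so a
# seed argument fully determines their output (no global state).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort_fnirseeg("`seed` must be a single finite number", "invalid_parameter")
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort_fnirseeg(sprintf("`%s` must be a single positive number", name),
                   "invalid_parameter")
  }
  invisible(x)
}

rms <- function(x) sqrt(mean(x^2))
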