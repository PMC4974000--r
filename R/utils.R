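# Internal helpers: reproducible RNG substreams and seed-preserving evaluation.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Named substreams fan out from one master seed so each pipeline stage is
# independently reproducible. Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stream) {
  streams <- c(
    eye_selection = 1, simulation = 2, bootstrap = 3,
    recovery = 4, markers = 5, pipeline = 6
  )
  if (!stream %in% names(streams)) {
    abort(paste0("unknown RNG substream '", stream, "'"))
  }
  k <- streams[[stream]]
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + k * 7919) %% 2147483647)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
  if (x < lower || x > upper) {
    abort(paste0("`", name, "` must be in [", lower, ", ", upper, "]"))
  }
  invisible(x)
}
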