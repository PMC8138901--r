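# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic per-stage substream seed derived from one root seed.
# Keeps results reproducible while decoupling the stages' random draws.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

abort <- function(...) stop(..., call. = FALSE)

# Resolve an "integer or range" field to one draw per unit.
draw_count <- function(x, n) {
  if (length(x) == 1L) rep(as.integer(x), n)
  else sample(seq.int(x[1], x[2]), n, replace = TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("'%s' must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
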