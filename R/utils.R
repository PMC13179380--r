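#' @keywords internal
"_PACKAGE"

# Labeled error helper: every user-facing validation failure goes through this
# so tests can match on class.
sf_stop <- function(msg, class = "stressfuse_error", ...) {
  stop(structure(
    class = c(class, "stressfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sf_assert <- function(cond, msg, class = "stressfuse_error") {
  if (!isTRUE(cond)) sf_stop(msg, class = class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit seed mixing. Distinct streams for (master seed, tags)
# without a hashing dependency; keeps every derived seed below 2^31.
mix_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  })))
  h <- 0
  for (p in parts) {
    h <- (h * 1000003 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Population (divide-by-n) variance and SD: the package-wide convention for
# HRV statistics so closed-form oracles are unambiguous.
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))
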