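#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-stream seed
#'
#' Hashes a master seed together with string tokens into a 31-bit integer,
#' so every simulated sample gets its own deterministic RNG stream.
#'
#' @param seed Integer master seed.
#' @param ... Character/numeric tokens identifying the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, ...) {
  m <- 2147483647
  s <- abs(as.double(seed)) %% m
  tokens <- as.character(unlist(list(...), use.names = FALSE))
  for (tok in tokens) {
    for (code in utf8ToInt(tok)) s <- (s * 31 + code) %% m
    s <- (s * 31 + 7) %% m  # token separator so c("ab","c") != c("a","bc")
  }
  as.integer(s)
}

# internal: stop with a consistent message prefix
os_stop <- function(...) stop(..., call. = FALSE)

os_warn <- function(...) warning(..., call. = FALSE)

# internal: check a numeric scalar lies in an open interval
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= lo || x >= hi) {
    os_stop(sprintf("`%s` must be a single number in (%g, %g)", name, lo, hi))
  }
  invisible(x)
}
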