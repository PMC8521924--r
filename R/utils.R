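# Internal helpers shared across modules.

# Classed error constructors so the CLI can map error classes to exit codes.
stop_eegsweep <- function(msg, class) {
  rlang::abort(msg, class = c(class, "eegsweep_error"))
}
stop_format <- function(msg) stop_eegsweep(msg, "eegsweep_format_error")
stop_param  <- function(msg) stop_eegsweep(msg, "eegsweep_parameter_error")
stop_contract <- function(msg) stop_eegsweep(msg, "eegsweep_contract_error")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-stream seed derivation (counter-based): folds integer keys
# into a MINSTD-style recurrence mod 2^31 - 1 so per-epoch / per-model draws
# are order-independent and reproducible from one global seed. Multipliers are
# small enough that all intermediates stay exact in double precision.
sub_seed <- function(seed, ...) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (k in c(...)) {
    s <- (s * 48271 + (abs(as.numeric(k)) %% m) * 12347 + 1) %% m
  }
  as.integer(s)
}

# Evaluate expr under a temporary RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Maximal runs of TRUE in a logical vector; returns a matrix with 1-based
# inclusive start/end columns (possibly 0 rows).
runs_true <- function(flag) {
  n <- length(flag)
  if (n == 0L || !any(flag)) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
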