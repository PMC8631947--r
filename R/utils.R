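# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483647)
}

#' Wrap an angular difference into (-90, 90] degrees (orientation space)
#' @param x angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap180 <- function(x) {
  y <- x %% 180
  ifelse(y > 90, y - 180, y)
}

# Wrap direction into [0, 360).
wrap360 <- function(x) x %% 360

# Rolling minimum over `k` consecutive samples; result[i] = min(x[i..i+k-1]),
# length(x) - k + 1 values. Works on vectors and matrix rows.
roll_min <- function(x, k) {
  n <- length(x)
  if (n < k) return(numeric(0))
  out <- x[seq_len(n - k + 1)]
  for (j in seq_len(k - 1)) out <- pmin(out, x[seq_len(n - k + 1) + j])
  out
}

roll_min_rows <- function(m, k) {
  n <- ncol(m)
  stopifnot(n >= k)
  out <- m[, seq_len(n - k + 1), drop = FALSE]
  for (j in seq_len(k - 1)) out <- pmin(out, m[, seq_len(n - k + 1) + j, drop = FALSE])
  out
}

# Earliest index i with x[i..i+k-1] all >= threshold, NA if none.
first_sustained <- function(x, threshold, k) {
  rm_ <- roll_min(x, k)
  i <- which(rm_ >= threshold)
  if (length(i) == 0) NA_integer_ else i[1]
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
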