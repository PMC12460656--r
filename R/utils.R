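#' @useDynLib dreamcomplexity, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile rnorm runif sd pnorm aggregate setNames
#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
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
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic sub-seed derivation so that parallel structures (channels,
# epochs, participants) get independent, order-invariant streams. Kept below
# 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed %% 2147483647L)
  for (v in idx) {
    x <- (x * 48271 + as.double(v) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# moving-average smoother with reflecting edges; width in samples
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  n <- length(x)
  half <- min(half, n)  # clamp for very short series
  width <- 2L * half + 1L
  xp <- c(rev(x[seq_len(half)]), x, rev(x[seq.int(n - half + 1L, n)]))
  cs <- cumsum(c(0, xp))
  i <- (half + 1L):(half + n)  # positions of x within xp
  (cs[i + half + 1L] - cs[i - half]) / width
}
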