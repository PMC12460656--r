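#' Parameters for the state-transition perturbational complexity index
#'
#' Defaults pin the analysis windows inside the -250..+500 ms TMS epoch
#' (baseline -250..-5 ms, response 0..300 ms), retain principal components
#' up to 99% of response-window variance (at most 10), weight baseline
#' transitions by `k_weight = 1.2` in the threshold objective, search 100
#' candidate thresholds, and drop components whose response/baseline
#' amplitude ratio falls below 1.1.
#'
#' @param baseline_window `c(start_ms, end_ms)`, entirely pre-stimulus.
#' @param response_window `c(start_ms, end_ms)`, entirely post-stimulus.
#' @param variance_retained fraction of response-window variance the
#'   retained components must reach, in `(0, 1]`.
#' @param max_components cap on the number of retained components.
#' @param k_weight weighting (`>= 1`) of baseline transitions in the
#'   threshold-selection objective.
#' @param epsilon_grid_size number of candidate thresholds.
#' @param min_component_snr minimum response/baseline RMS ratio for a
#'   component to be retained.
#' @return an object of class `pcist_params`.
#' @export
pcist_params <- function(baseline_window = c(-250, -5),
                         response_window = c(0, 300),
                         variance_retained = 0.99,
                         max_components = 10L,
                         k_weight = 1.2,
                         epsilon_grid_size = 100L,
                         min_component_snr = 1.1) {
  if (!(baseline_window[1] < baseline_window[2] && baseline_window[2] <= 0)) {
    stop("`baseline_window` must lie entirely before 0 ms", call. = FALSE)
  }
  if (!(response_window[1] >= 0 && response_window[1] < response_window[2])) {
    stop("`response_window` must lie entirely at/after 0 ms", call. = FALSE)
  }
  if (!(variance_retained > 0 && variance_retained <= 1)) {
    stop("`variance_retained` must be in (0, 1]", call. = FALSE)
  }
  if (k_weight < 1) stop("`k_weight` must be >= 1", call. = FALSE)
  structure(
    list(baseline_window = baseline_window, response_window = response_window,
         variance_retained = variance_retained,
         max_components = as.integer(max_components),
         k_weight = k_weight,
         epsilon_grid_size = as.integer(epsilon_grid_size),
         min_component_snr = min_component_snr),
    class = "pcist_params"
  )
}

# half-open [start, end) window selection on a time axis in ms
window_index <- function(times, win) {
  which(times >= win[1] & times < win[2])
}

#' Trial-average a TMS-evoked trial set
#'
#' Pointwise mean over trials, followed by baseline correction (per-channel
#' mean over the baseline window subtracted) and re-referencing to the
#' channel average (so the channel mean is 0 at every time point).
#'
#' @param t a [tep_set()].
#' @param baseline_window `c(start_ms, end_ms)` used for the correction.
#' @return a `channels x time` matrix with attribute `times` (ms).
#' @export
trial_average <- function(t, baseline_window = c(-250, -5)) {
  if (!inherits(t, "tep_set")) stop("`t` must be a tep_set", call. = FALSE)
  d <- dim(t$data)
  evoked <- matrix(0, d[2L], d[3L])
  for (tr in seq_len(d[1L])) evoked <- evoked + t$data[tr, , ]
  evoked <- evoked / d[1L]
  bidx <- window_index(t$times, baseline_window)
  if (length(bidx) > 0L) {
    evoked <- evoked - rowMeans(evoked[, bidx, drop = FALSE])
  }
  evoked <- sweep(evoked, 2L, colMeans(evoked))  # average reference
  attr(evoked, "times") <- t$times
  evoked
}

#' Principal-component time courses of a trial-averaged evoked response
#'
#' Singular value decomposition of the response-window segment of the
#' evoked matrix; the spatial singular vectors project the full epoch onto
#' component time courses carrying the singular-value amplitude scale.
#' The smallest component set reaching `variance_retained` of the
#' response-window variance is kept (capped at `max_components`), and
#' components whose response/baseline RMS ratio is below
#' `min_component_snr` are dropped.
#'
#' @param evoked `channels x time` matrix from [trial_average()] with a
#'   `times` attribute, or pass `times` explicitly.
#' @param p a [pcist_params()].
#' @param times per-sample times in ms (defaults to `attr(evoked, "times")`).
#' @return list with `timecourses` (retained components x time),
#'   `times`, `singular_values`, `n_retained`.
#' @export
pca_components <- function(evoked, p = pcist_params(), times = attr(evoked, "times")) {
  if (is.null(times)) stop("`times` must be supplied", call. = FALSE)
  ridx <- window_index(times, p$response_window)
  bidx <- window_index(times, p$baseline_window)
  if (length(ridx) < 2L || length(bidx) < 2L) {
    stop("evoked matrix does not contain both analysis windows", call. = FALSE)
  }
  resp <- evoked[, ridx, drop = FALSE]
  total <- sum(resp^2)
  empty <- list(timecourses = matrix(0, 0L, ncol(evoked)), times = times,
                singular_values = numeric(0), n_retained = 0L)
  if (total == 0) return(empty)
  sv <- svd(resp)
  varfrac <- cumsum(sv$d^2) / sum(sv$d^2)
  m <- which(varfrac >= p$variance_retained)[1L]
  m <- min(m, p$max_components, length(sv$d))
  keep <- seq_len(m)[sv$d[seq_len(m)] > 0]
  if (length(keep) == 0L) return(empty)
  tc <- t(sv$u[, keep, drop = FALSE]) %*% evoked  # m x time, amplitude-scaled
  rms <- function(z) sqrt(mean(z^2))
  snr <- vapply(seq_len(nrow(tc)), function(i) {
    b <- rms(tc[i, bidx]); r <- rms(tc[i, ridx])
    if (b == 0) Inf else r / b
  }, numeric(1))
  ok <- snr >= p$min_component_snr
  list(timecourses = tc[ok, , drop = FALSE], times = times,
       singular_values = sv$d[keep][ok], n_retained = sum(ok))
}

#' Pointwise amplitude-distance matrix of a component segment
#'
#' @param y numeric vector (length `>= 2`).
#' @return symmetric matrix `D[i, j] = |y[i] - y[j]|` with zero diagonal.
#' @export
distance_matrix <- function(y) {
  if (length(y) < 2L) stop("`y` must have length >= 2", call. = FALSE)
  abs(outer(y, y, "-"))
}

#' Mean number of state transitions of a thresholded distance matrix
#'
#' Binarizes the distance matrix as `T = 1[D > eps]` and counts, for each
#' reference time point (column), the transitions along time
#' `sum_t |T[t+1, t'] - T[t, t']|`; the mean over reference columns is
#' returned.
#'
#' @param y component segment (numeric vector).
#' @param eps threshold (`>= 0`).
#' @return mean transition count (dimensionless, `>= 0`).
#' @examples
#' nst(c(0, 0, 1, 1), 0.5)  # 1
#' @export
nst <- function(y, eps) {
  if (eps < 0) stop("`eps` must be >= 0", call. = FALSE)
  Tm <- distance_matrix(y) > eps
  mean(colSums(abs(diff(Tm))))  # diff() runs down columns (along time)
}

# NST evaluated on a whole ascending grid of thresholds at once.
# A column transition between rows t and t+1 exists iff
# min(D[t,], D[t+1,]) <= eps < max(D[t,], D[t+1,]) (strict `>` binarization),
# so the total transition count is #(lo <= eps) - #(hi <= eps); sorted
# adjacent-pair bounds turn the whole grid into two findInterval calls.
nst_grid <- function(y, eps_grid) {
  L <- length(y)
  D <- abs(outer(y, y, "-"))
  D1 <- D[-L, , drop = FALSE]
  D2 <- D[-1L, , drop = FALSE]
  lo <- sort(pmin(D1, D2))
  hi <- sort(pmax(D1, D2))
  (findInterval(eps_grid, lo) - findInterval(eps_grid, hi)) / L
}

#' Optimize the binarization threshold for one component
#'
#' Candidate thresholds are `epsilon_grid_size` quantiles of the pooled
#' distance values of both segments. The selected threshold maximizes the
#' per-sample weighted contrast
#' `NST_resp(eps)/L_resp - k_weight * NST_base(eps)/L_base`; ties are
#' broken toward the smaller threshold.
#'
#' @param y_base baseline component segment.
#' @param y_resp response component segment.
#' @param p a [pcist_params()].
#' @return list with `epsilon`, `objective`, `nst_base`, `nst_resp`.
#' @export
optimize_epsilon <- function(y_base, y_resp, p = pcist_params()) {
  if (length(y_base) < 2L || length(y_resp) < 2L) {
    stop("both segments must be nonempty (length >= 2)", call. = FALSE)
  }
  pool <- c(distance_matrix(y_base)[upper.tri(diag(length(y_base)))],
            distance_matrix(y_resp)[upper.tri(diag(length(y_resp)))])
  grid <- unname(quantile(pool, probs = seq(0, 1, length.out = p$epsilon_grid_size),
                          type = 7))
  Lb <- length(y_base); Lr <- length(y_resp)
  nst_b <- nst_grid(y_base, grid)
  nst_r <- nst_grid(y_resp, grid)
  obj <- nst_r / Lr - p$k_weight * nst_b / Lb
  i <- which.max(obj)  # grid ascending: first max = smallest epsilon
  list(epsilon = grid[i], objective = obj[i],
       nst_base = nst_b[i], nst_resp = nst_r[i])
}

#' State-transition perturbational complexity index of a TMS-evoked trial set
#'
#' Pipeline: trial averaging (with baseline correction and average
#' reference), principal-component decomposition of the response window,
#' and for each retained component a threshold optimized by
#' [optimize_epsilon()]; the component contribution is the
#' response-length-scaled excess transition rate
#' `dNST = L_resp * (NST_resp/L_resp - NST_base/L_base)` at the optimum,
#' negative contributions clipped to 0. The index is the sum over
#' components.
#'
#' @param t a [tep_set()].
#' @param p a [pcist_params()].
#' @return an object of class `pcist_result` with fields `value`,
#'   `per_component` (tibble: `component`, `epsilon`, `nst_base`,
#'   `nst_resp`, `dnst`), `n_components_retained`.
#' @export
pcist <- function(t, p = pcist_params()) {
  evoked <- trial_average(t, baseline_window = p$baseline_window)
  comps <- pca_components(evoked, p)
  times <- comps$times
  bidx <- window_index(times, p$baseline_window)
  ridx <- window_index(times, p$response_window)
  Lb <- length(bidx); Lr <- length(ridx)
  m <- comps$n_retained
  per <- tibble::tibble(component = integer(0), epsilon = numeric(0),
                        nst_base = numeric(0), nst_resp = numeric(0),
                        dnst = numeric(0))
  if (m > 0L) {
    rows <- lapply(seq_len(m), function(i) {
      y <- comps$timecourses[i, ]
      opt <- optimize_epsilon(y[bidx], y[ridx], p)
      dnst <- Lr * (opt$nst_resp / Lr - opt$nst_base / Lb)
      tibble::tibble(component = i, epsilon = opt$epsilon,
                     nst_base = opt$nst_base, nst_resp = opt$nst_resp,
                     dnst = max(0, dnst))
    })
    per <- dplyr::bind_rows(rows)
  }
  structure(
    list(value = sum(per$dnst), per_component = per,
         n_components_retained = m),
    class = "pcist_result"
  )
}

#' @export
print.pcist_result <- function(x, ...) {
  cat(sprintf("<pcist_result> PCIst = %.3f over %d components\n",
              x$value, x$n_components_retained))
  invisible(x)
}

#' @rdname pcist
#' @param x a `pcist_result`.
#' @param ... unused.
#' @export
tidy.pcist_result <- function(x, ...) x$per_component

#' @rdname pcist
#' @export
glance.pcist_result <- function(x, ...) {
  tibble::tibble(value = x$value,
                 n_components_retained = x$n_components_retained)
}

#' Global mean field power of an evoked response
#'
#' The across-channel standard deviation (denominator `n - 1`) of the
#' instantaneous values at each time point; for two channels at `+a`/`-a`
#' this equals `|a| * sqrt(2)`.
#'
#' @param evoked `channels x time` matrix (`>= 2` channels).
#' @return numeric time series.
#' @export
gmfp <- function(evoked) {
  if (nrow(evoked) < 2L) stop("`evoked` must have >= 2 channels", call. = FALSE)
  apply(evoked, 2L, sd)
}

#' Inter-trial phase coherence of a trial set in a frequency band
#'
#' Each trial/channel is band-pass filtered (4th-order zero-phase
#' Butterworth), the analytic phase extracted, and the ITPC computed as the
#' modulus of the trial-mean unit phase vector.
#'
#' @param t a [tep_set()] with `>= 2` trials.
#' @param band `c(low_hz, high_hz)`.
#' @return `channels x time` matrix of coherence values in `[0, 1]`.
#' @export
itpc <- function(t, band = c(8, 12)) {
  if (!inherits(t, "tep_set")) stop("`t` must be a tep_set", call. = FALSE)
  d <- dim(t$data)
  if (d[1L] < 2L) stop("`t` must contain >= 2 trials", call. = FALSE)
  bf <- signal::butter(4, band / (t$fs / 2), type = "pass")
  acc <- matrix(0 + 0i, d[2L], d[3L])
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      xf <- signal::filtfilt(bf, t$data[tr, ch, ])
      n <- length(xf)
      h <- numeric(n)
      if (n %% 2L == 0L) { h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2 }
      else { h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2 }
      z <- fft(fft(xf) * h, inverse = TRUE) / n
      ph <- z / Mod(z)
      ph[Mod(z) == 0] <- 0 + 0i
      acc[ch, ] <- acc[ch, ] + ph
    }
  }
  Mod(acc) / d[1L]
}
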