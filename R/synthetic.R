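#' Spectral state profile for synthetic spontaneous EEG
#'
#' A `state_profile` parameterizes the synthetic spontaneous-EEG generator:
#' relative amplitudes of band-limited oscillators (delta 0.5-4 Hz, theta
#' 4-8, alpha 8-12, beta 13-30), the spectral slope of the 1/f^alpha
#' background, and the broadband RMS amplitude in microvolts.
#'
#' The three packaged profiles emulate the recorded conditions of a
#' serial-awakening sedation study: wake eyes-open (`wake_eo`, flattest
#' spectrum), wake eyes-closed (`wake_ec`, alpha amplitude doubled relative
#' to eyes-open), and deep propofol sedation (`sedation`, dominant slow-wave
#' amplitude and a steeper background slope). All three share the same
#' broadband RMS so condition contrasts are spectral, not gain, effects.
#'
#' @param name one of `"wake_eo"`, `"wake_ec"`, `"sedation"`, or any label
#'   when `band_powers` is given explicitly.
#' @param band_powers named numeric vector `c(delta=, theta=, alpha=, beta=)`
#'   of relative oscillator amplitudes (dimensionless, all `>= 0`).
#' @param one_over_f_exponent spectral slope alpha of the background.
#' @param broadband_rms background RMS amplitude, microvolts (`> 0` unless a
#'   fully silent profile is requested with all powers 0).
#' @return an object of class `state_profile`.
#' @examples
#' state_profile("sedation")
#' @export
state_profile <- function(name = c("wake_eo", "wake_ec", "sedation"),
                          band_powers = NULL,
                          one_over_f_exponent = NULL,
                          broadband_rms = NULL) {
  defaults <- list(
    wake_eo  = list(bp = c(delta = 1.0, theta = 0.5, alpha = 1.0, beta = 0.7),
                    expo = 1.0, rms = 10),
    wake_ec  = list(bp = c(delta = 1.0, theta = 0.5, alpha = 2.0, beta = 0.7),
                    expo = 1.0, rms = 10),
    sedation = list(bp = c(delta = 4.0, theta = 1.0, alpha = 0.5, beta = 0.3),
                    expo = 1.8, rms = 10)
  )
  if (is.null(band_powers) || is.null(one_over_f_exponent) || is.null(broadband_rms)) {
    name <- match.arg(name)
    def <- defaults[[name]]
    if (is.null(band_powers)) band_powers <- def$bp
    if (is.null(one_over_f_exponent)) one_over_f_exponent <- def$expo
    if (is.null(broadband_rms)) broadband_rms <- def$rms
  } else {
    name <- as.character(name)[1L]
  }
  bands <- c("delta", "theta", "alpha", "beta")
  if (!all(bands %in% names(band_powers))) {
    stop("`band_powers` must be named with delta, theta, alpha, beta", call. = FALSE)
  }
  band_powers <- band_powers[bands]
  if (any(band_powers < 0)) stop("band powers must be >= 0", call. = FALSE)
  if (broadband_rms < 0) stop("`broadband_rms` must be >= 0", call. = FALSE)
  if (broadband_rms == 0 && any(band_powers > 0)) {
    stop("`broadband_rms` must be > 0 for a non-silent profile", call. = FALSE)
  }
  structure(
    list(name = name, band_powers = band_powers,
         one_over_f_exponent = one_over_f_exponent,
         broadband_rms = broadband_rms),
    class = "state_profile"
  )
}

#' @export
print.state_profile <- function(x, ...) {
  cat(sprintf("<state_profile> %s: 1/f^%.2g, rms %g uV; bands %s\n",
              x$name, x$one_over_f_exponent, x$broadband_rms,
              paste(sprintf("%s=%g", names(x$band_powers), x$band_powers),
                    collapse = " ")))
  invisible(x)
}

# band edges in Hz
.band_edges <- list(delta = c(0.5, 4), theta = c(4, 8),
                    alpha = c(8, 12), beta = c(13, 30))

# 1/f^alpha noise with spectral support restricted to band_lim, unit RMS
pink_noise <- function(n, alpha, fs, band_lim = c(0.5, 45)) {
  freqs <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
  mag <- numeric(length(freqs))
  sel <- freqs >= band_lim[1] & freqs <= min(band_lim[2], fs / 2)
  mag[sel] <- freqs[sel]^(-alpha / 2)
  ph <- runif(length(freqs), 0, 2 * pi)
  half <- mag * exp(1i * ph)
  half[1L] <- 0
  if (n %% 2L == 0L) half[length(half)] <- Re(half[length(half)])
  spec <- c(half, Conj(rev(half[2:(length(half) - (1 - n %% 2L))])))
  x <- Re(fft(spec, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# slow positive amplitude-modulation envelope, mean ~1
am_envelope <- function(n, fs) {
  z <- rnorm(n)
  z <- smooth_ma(z, width = round(1.5 * fs))
  s <- sd(z)
  if (s > 0) z <- z / s
  pmax(0, 1 + 0.6 * z)
}

# random unit-norm channel topography, smoothed over a 1-D channel ordering
smooth_topography <- function(n_channels) {
  v <- rnorm(n_channels)
  if (n_channels > 2L) v <- smooth_ma(v, width = max(3L, round(n_channels / 3)))
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else rep(1 / sqrt(n_channels), n_channels)
}

#' Generate synthetic multichannel spontaneous EEG
#'
#' Each channel is the sum of an independent 1/f^alpha background (band
#' limited to 0.5-45 Hz, emulating the band-pass of a cleaned recording) and
#' amplitude-modulated band-limited oscillators with random carrier
#' frequency and phase, mixed into channels through smooth random unit-norm
#' topographies. The recording is cut into 5-second epochs
#' (`floor(duration/5)` of them). Identical seeds give bitwise-identical
#' output.
#'
#' @param profile a [state_profile()].
#' @param n_channels number of channels (`>= 1`).
#' @param duration recording length in seconds (`>= 5`).
#' @param fs sampling rate in Hz (`>= 100`).
#' @param seed integer seed.
#' @param oscillators_per_band number of oscillators per frequency band.
#' @return an `epoch_set` of 5-second epochs.
#' @examples
#' e <- gen_spontaneous(state_profile("wake_eo"), n_channels = 4,
#'                      duration = 10, fs = 250, seed = 1)
#' dim(e)
#' @export
gen_spontaneous <- function(profile, n_channels, duration, fs, seed,
                            oscillators_per_band = 2L) {
  if (!inherits(profile, "state_profile")) {
    stop("`profile` must be a state_profile", call. = FALSE)
  }
  stopifnot_scalar_number(n_channels, "n_channels", positive = TRUE)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (duration < 5) stop("`duration` must be >= 5 s (one epoch)", call. = FALSE)
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  n_channels <- as.integer(n_channels)
  n_ep <- floor(duration / 5)
  n <- as.integer(n_ep * 5 * fs)
  tt <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    x <- matrix(0, n_channels, n)
    if (profile$broadband_rms > 0) {
      for (ch in seq_len(n_channels)) {
        x[ch, ] <- profile$broadband_rms *
          pink_noise(n, profile$one_over_f_exponent, fs)
      }
      for (band in names(profile$band_powers)) {
        amp <- profile$band_powers[[band]] * profile$broadband_rms
        if (amp <= 0) next
        edges <- .band_edges[[band]]
        for (k in seq_len(oscillators_per_band)) {
          f0 <- runif(1, edges[1], edges[2])
          phi <- runif(1, 0, 2 * pi)
          env <- am_envelope(n, fs)
          osc <- amp * env * cos(2 * pi * f0 * tt + phi)
          topo <- smooth_topography(n_channels)
          x <- x + outer(topo, osc)
        }
      }
    }
    epoch_continuous(x, fs = fs, epoch_length = 5)
  })
}

#' Specification of a synthetic TMS-evoked response
#'
#' Describes a deterministic evoked waveform as a sum of `k` damped cosines,
#' each with its own frequency, damping time constant, onset latency,
#' amplitude and (smooth random unit-norm) channel topography, plus the
#' trial noise level and trial count. Used by [gen_tep()].
#'
#' @param k number of evoked components (`>= 0`).
#' @param freqs per-component frequencies, Hz.
#' @param damping per-component damping time constants, ms.
#' @param latencies per-component onset latencies, ms (all `>= 0`).
#' @param amplitudes per-component amplitudes, microvolts.
#' @param trial_noise_rms per-trial background noise RMS, microvolts.
#' @param n_trials number of trials (`>= 1`).
#' @param total_energy optional target for the summed squared amplitude of
#'   the evoked waveform; when given, component amplitudes are rescaled so
#'   specs with different `k` have matched evoked energy.
#' @return an object of class `tep_spec`.
#' @export
tep_spec <- function(k = 8L,
                     freqs = NULL, damping = NULL, latencies = NULL,
                     amplitudes = NULL,
                     trial_noise_rms = 4, n_trials = 100L,
                     total_energy = NULL) {
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0", call. = FALSE)
  if (k > 0L) {
    if (is.null(freqs)) freqs <- seq(6, 34, length.out = k)
    if (is.null(damping)) damping <- seq(90, 40, length.out = k)
    if (is.null(latencies)) latencies <- seq(15, 220, length.out = k)
    if (is.null(amplitudes)) amplitudes <- seq(8, 3, length.out = k)
    lens <- c(length(freqs), length(damping), length(latencies), length(amplitudes))
    if (any(lens != k)) {
      stop("component parameter vectors must all have length `k`", call. = FALSE)
    }
    if (any(latencies < 0)) stop("latencies must be >= 0", call. = FALSE)
  } else {
    freqs <- damping <- latencies <- amplitudes <- numeric(0)
  }
  if (trial_noise_rms < 0) stop("`trial_noise_rms` must be >= 0", call. = FALSE)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  structure(
    list(k = k, freqs = freqs, damping = damping, latencies = latencies,
         amplitudes = amplitudes, trial_noise_rms = trial_noise_rms,
         n_trials = as.integer(n_trials), total_energy = total_energy),
    class = "tep_spec"
  )
}

#' @export
print.tep_spec <- function(x, ...) {
  cat(sprintf("<tep_spec> k=%d components, %d trials, noise rms %g uV\n",
              x$k, x$n_trials, x$trial_noise_rms))
  invisible(x)
}

#' Generate a synthetic TMS-evoked trial set
#'
#' Every trial is independent 1/f background noise plus one identical
#' deterministic evoked waveform (sum of damped cosines per [tep_spec()])
#' added only at post-stimulus times. The epoch covers
#' `epoch_window[1]..epoch_window[2]` ms around the pulse at time 0.
#' Identical seeds give bitwise-identical output.
#'
#' @param spec a [tep_spec()].
#' @param n_channels number of channels.
#' @param fs sampling rate, Hz.
#' @param epoch_window `c(start_ms, end_ms)` spanning negative to positive
#'   times; default `c(-250, 500)`.
#' @param seed integer seed.
#' @return a `tep_set`.
#' @export
gen_tep <- function(spec, n_channels, fs, epoch_window = c(-250, 500), seed) {
  if (!inherits(spec, "tep_spec")) stop("`spec` must be a tep_spec", call. = FALSE)
  stopifnot_scalar_number(n_channels, "n_channels", positive = TRUE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0)) {
    stop("`epoch_window` must span negative to positive times", call. = FALSE)
  }
  if (spec$k > 0L && any(spec$latencies >= epoch_window[2])) {
    stop("component latency outside the response window", call. = FALSE)
  }
  n_channels <- as.integer(n_channels)
  i0 <- floor(epoch_window[1] / 1000 * fs)
  i1 <- ceiling(epoch_window[2] / 1000 * fs)
  times <- (i0:(i1 - 1L)) / fs * 1000  # ms; half-open [start, end)
  n <- length(times)
  with_seed(seed, {
    # deterministic evoked waveform, channels x time
    evoked <- matrix(0, n_channels, n)
    if (spec$k > 0L) {
      topo <- vapply(seq_len(spec$k), function(i) smooth_topography(n_channels),
                     numeric(n_channels))
      topo <- matrix(topo, nrow = n_channels)
      amps <- spec$amplitudes
      waves <- matrix(0, spec$k, n)
      for (i in seq_len(spec$k)) {
        tl <- (times - spec$latencies[i]) / 1000  # s since onset
        w <- ifelse(times >= spec$latencies[i] & times >= 0,
                    exp(-tl * 1000 / spec$damping[i]) * cos(2 * pi * spec$freqs[i] * tl),
                    0)
        waves[i, ] <- w
      }
      if (!is.null(spec$total_energy)) {
        raw <- 0
        for (i in seq_len(spec$k)) raw <- raw + sum((amps[i] * waves[i, ])^2)
        if (raw > 0) amps <- amps * sqrt(spec$total_energy / raw)
      }
      for (i in seq_len(spec$k)) {
        evoked <- evoked + outer(topo[, i], amps[i] * waves[i, ])
      }
    }
    data <- array(0, c(spec$n_trials, n_channels, n))
    for (tr in seq_len(spec$n_trials)) {
      noise <- matrix(0, n_channels, n)
      if (spec$trial_noise_rms > 0) {
        for (ch in seq_len(n_channels)) {
          noise[ch, ] <- spec$trial_noise_rms * pink_noise(n, 1, fs)
        }
      }
      data[tr, , ] <- noise + evoked
    }
    tep_set(data, fs = fs, times = times)
  })
}

#' Marginal counts of awakening reports
#'
#' Marginal distributions of the two report questions and of the three-class
#' experience classification over a set of awakenings. The default is the
#' packaged 52-awakening study distribution: Q1 (what did you experience?)
#' nothing/no_info/white/vague/vivid = 1/28/2/9/12; Q2 (did you experience
#' anything?) no/no_info/maybe/yes = 8/22/4/18; classes
#' experience/no_information/no_experience = 24/23/5.
#'
#' @param q1_counts named integer vector over
#'   `c("nothing","no_info","white","vague","vivid")`.
#' @param q2_counts named integer vector over
#'   `c("no","no_info","maybe","yes")`.
#' @param class_totals named integer vector over
#'   `c("experience","no_information","no_experience")`.
#' @return an object of class `report_marginals`.
#' @export
report_marginals <- function(
    q1_counts = c(nothing = 1L, no_info = 28L, white = 2L, vague = 9L, vivid = 12L),
    q2_counts = c(no = 8L, no_info = 22L, maybe = 4L, yes = 18L),
    class_totals = c(experience = 24L, no_information = 23L, no_experience = 5L)) {
  q1_lv <- c("nothing", "no_info", "white", "vague", "vivid")
  q2_lv <- c("no", "no_info", "maybe", "yes")
  cl_lv <- c("experience", "no_information", "no_experience")
  if (!all(q1_lv %in% names(q1_counts))) stop("q1_counts incomplete", call. = FALSE)
  if (!all(q2_lv %in% names(q2_counts))) stop("q2_counts incomplete", call. = FALSE)
  if (!all(cl_lv %in% names(class_totals))) stop("class_totals incomplete", call. = FALSE)
  q1_counts <- as.integer(q1_counts[q1_lv]); names(q1_counts) <- q1_lv
  q2_counts <- as.integer(q2_counts[q2_lv]); names(q2_counts) <- q2_lv
  class_totals <- as.integer(class_totals[cl_lv]); names(class_totals) <- cl_lv
  n <- sum(q1_counts)
  if (sum(q2_counts) != n || sum(class_totals) != n) {
    stop(sprintf(
      "infeasible marginals: totals differ (q1 %d, q2 %d, classes %d)",
      n, sum(q2_counts), sum(class_totals)), call. = FALSE)
  }
  if (any(q1_counts < 0) || any(q2_counts < 0) || any(class_totals < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(
    list(q1_counts = q1_counts, q2_counts = q2_counts,
         class_totals = class_totals, n_awakenings = n),
    class = "report_marginals"
  )
}

#' @export
print.report_marginals <- function(x, ...) {
  cat(sprintf("<report_marginals> n=%d; Q1 %s; Q2 %s; classes %s\n",
              x$n_awakenings,
              paste(x$q1_counts, collapse = "/"),
              paste(x$q2_counts, collapse = "/"),
              paste(x$class_totals, collapse = "/")))
  invisible(x)
}

#' Reconstruct a Q1 x Q2 joint contingency table consistent with marginals
#'
#' Finds, by deterministic backtracking search (cells visited in
#' lexicographic (Q1 row, Q2 column) order, candidate counts tried in
#' ascending order), a nonnegative integer 5 x 4 table whose row sums equal
#' the Q1 marginals, whose column sums equal the Q2 marginals, and whose
#' class totals under the given classification rule equal the class
#' marginals. The first table found is returned, so the result is a fixed,
#' reproducible fixture.
#'
#' @param marginals a [report_marginals()].
#' @param rule a classification rule from [classification_rule()].
#' @return an integer matrix with Q1 categories as rows and Q2 categories as
#'   columns.
#' @examples
#' tab <- fixture_joint_table(report_marginals())
#' sum(tab)  # 52
#' @export
fixture_joint_table <- function(marginals = report_marginals(),
                                rule = classification_rule()) {
  if (!inherits(marginals, "report_marginals")) {
    stop("`marginals` must be report_marginals", call. = FALSE)
  }
  q1_lv <- names(marginals$q1_counts)
  q2_lv <- names(marginals$q2_counts)
  nr <- length(q1_lv); nc <- length(q2_lv)
  cell_class <- matrix("", nr, nc, dimnames = list(q1_lv, q2_lv))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cell_class[i, j] <- classify_awakening(q1_lv[i], q2_lv[j], rule = rule)
  }
  key <- paste(c(marginals$q1_counts, marginals$q2_counts,
                 marginals$class_totals, as.vector(cell_class)), collapse = "|")
  cached <- .joint_table_cache[[key]]
  if (!is.null(cached)) return(cached)
  tab <- matrix(0L, nr, nc, dimnames = list(q1_lv, q2_lv))
  row_rem <- marginals$q1_counts
  col_rem <- marginals$q2_counts
  cls_rem <- marginals$class_totals
  # row totals still to be placed strictly below row i (for column pruning)
  suffix <- rev(cumsum(rev(as.numeric(marginals$q1_counts))))
  suffix <- c(suffix[-1L], 0)
  # upper bound on what rows strictly below i can contribute to each class
  cls_names <- names(cls_rem)
  row_has_class <- vapply(cls_names, function(cl) {
    rowSums(cell_class == cl) > 0
  }, logical(nr))
  cls_suffix <- vapply(cls_names, function(cl) {
    v <- as.numeric(marginals$q1_counts) * row_has_class[, cl]
    s <- rev(cumsum(rev(v)))
    c(s[-1L], 0)
  }, numeric(nr))

  solve_cell <- function(pos) {
    if (pos > nr * nc) return(all(col_rem == 0L) && all(cls_rem == 0L))
    i <- ((pos - 1L) %/% nc) + 1L
    j <- ((pos - 1L) %% nc) + 1L
    cl <- cell_class[i, j]
    cap <- min(row_rem[i], col_rem[j], cls_rem[cl])
    # rows below i can cover at most suffix[i] of column j's remaining
    # demand, so this cell must take at least the shortfall
    vmin <- max(0L, col_rem[j] - suffix[i])
    vals <- if (j == nc) {
      if (row_rem[i] >= vmin && row_rem[i] <= cap) row_rem[i] else integer(0)
    } else if (vmin <= cap) vmin:cap else integer(0)
    for (v in vals) {
      tab[i, j] <<- v
      row_rem[i] <<- row_rem[i] - v
      col_rem[j] <<- col_rem[j] - v
      cls_rem[cl] <<- cls_rem[cl] - v
      feasible <- TRUE
      if (j == nc) {
        # end of row i: every column and class must still be satisfiable by
        # the rows below
        if (any(col_rem > suffix[i]) || any(cls_rem > cls_suffix[i, ])) {
          feasible <- FALSE
        }
      }
      if (feasible && solve_cell(pos + 1L)) return(TRUE)
      tab[i, j] <<- 0L
      row_rem[i] <<- row_rem[i] + v
      col_rem[j] <<- col_rem[j] + v
      cls_rem[cl] <<- cls_rem[cl] + v
    }
    FALSE
  }
  if (!solve_cell(1L)) {
    stop("infeasible marginals: no joint table reproduces all three margins under this rule",
         call. = FALSE)
  }
  .joint_table_cache[[key]] <- tab
  tab
}

# memoization for fixture_joint_table (the search is deterministic)
.joint_table_cache <- new.env(parent = emptyenv())

#' Generate a table of awakening reports consistent with marginal counts
#'
#' Builds the deterministic joint Q1 x Q2 table with
#' [fixture_joint_table()], expands it into one `(q1, q2)` pair per
#' awakening, randomly permutes the pairs (uniformly, under the seed), and
#' assigns them to participants according to their awakening counts. The
#' default participant layout is 14 participants awoken 3 times, 4 awoken
#' twice, and 2 awoken once (52 awakenings over 20 participants).
#'
#' @param marginals a [report_marginals()].
#' @param participants integer vector of per-participant awakening counts;
#'   must sum to `marginals$n_awakenings`.
#' @param seed integer seed.
#' @param rule classification rule used to build the joint table.
#' @return a tibble with columns `participant_id`, `awakening_idx`,
#'   `q1`, `q2`.
#' @export
gen_reports <- function(marginals = report_marginals(),
                        participants = c(rep(3L, 14), rep(2L, 4), rep(1L, 2)),
                        seed = 1L,
                        rule = classification_rule()) {
  if (sum(participants) != marginals$n_awakenings) {
    stop(sprintf(
      "infeasible: participant awakening counts sum to %d but marginals give n_awakenings = %d",
      sum(participants), marginals$n_awakenings), call. = FALSE)
  }
  tab <- fixture_joint_table(marginals, rule)
  q1_lv <- rownames(tab); q2_lv <- colnames(tab)
  pairs <- do.call(rbind, lapply(seq_along(q1_lv), function(i) {
    do.call(rbind, lapply(seq_along(q2_lv), function(j) {
      if (tab[i, j] > 0L) {
        data.frame(q1 = rep(q1_lv[i], tab[i, j]), q2 = rep(q2_lv[j], tab[i, j]))
      }
    }))
  }))
  perm <- with_seed(seed, sample.int(nrow(pairs)))
  pairs <- pairs[perm, , drop = FALSE]
  pid <- sprintf("P%02d", seq_along(participants))
  tibble::tibble(
    participant_id = rep(pid, participants),
    awakening_idx = unlist(lapply(participants, seq_len), use.names = FALSE),
    q1 = factor(pairs$q1, levels = q1_lv),
    q2 = factor(pairs$q2, levels = q2_lv)
  )
}
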