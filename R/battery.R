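#' Assemble / validate a measure table
#'
#' A measure table holds one row per recording and measure:
#' `participant_id`, `condition` (one of `wake_eo`, `wake_ec`,
#' `sedation_1`..`sedation_3`), `measure` (`lzc` or `pcist`), `value`, and
#' `experience_class` (`NA` for wake rows). `(participant, condition,
#' measure)` must be unique and values finite.
#'
#' @param df a data frame with the columns above.
#' @return a tibble of class `measure_table`.
#' @export
as_measure_table <- function(df) {
  need <- c("participant_id", "condition", "measure", "value", "experience_class")
  if (!all(need %in% names(df))) {
    stop("measure table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)[, need]
  if (any(!is.finite(out$value))) stop("measure values must be finite", call. = FALSE)
  out <- dplyr::distinct(out)  # exact duplicate rows collapse harmlessly
  key <- paste(out$participant_id, out$condition, out$measure)
  if (anyDuplicated(key)) {
    stop("conflicting values for the same (participant, condition, measure)",
         call. = FALSE)
  }
  class(out) <- c("measure_table", class(out))
  out
}

# wake condition label for a measure: spontaneous LZc has both eye
# conditions; the TMS session (hence PCIst) was recorded eyes closed.
sedation_rows <- function(tab) {
  tab[grepl("^sedation", tab$condition), , drop = FALSE]
}

# per-participant mean over up to three sedation recordings of one measure
sedation_means <- function(tab, measure) {
  sed <- sedation_rows(tab)
  sed <- sed[sed$measure == measure, , drop = FALSE]
  if (nrow(sed) == 0L) return(setNames(numeric(0), character(0)))
  out <- aggregate(value ~ participant_id, data = as.data.frame(sed), FUN = mean)
  setNames(out$value, out$participant_id)
}

wake_values <- function(tab, measure, condition) {
  w <- tab[tab$measure == measure & tab$condition == condition, , drop = FALSE]
  setNames(w$value, w$participant_id)
}

# complete-case paired extraction: participants present on both sides
paired_values <- function(a, b) {
  ids <- intersect(names(a), names(b))
  list(x = unname(a[ids]), y = unname(b[ids]), n = length(ids),
       dropped = length(union(names(a), names(b))) - length(ids))
}

#' Run the full statistical battery on a measure table
#'
#' Reproduces the study's statistical layer: per-participant sedation means;
#' four matched-pairs Wilcoxon signed-rank comparisons (PCIst wake vs
#' sedation mean; LZc wake-eyes-open and wake-eyes-closed vs sedation mean;
#' LZc eyes-open vs eyes-closed); two random-intercept LMMs for the
#' experience-class effect on the sedation values of each measure;
#' Holm-Bonferroni correction across the six p-values; and 1.5-IQR outlier
#' flags per measure distribution. Missing pair members are dropped
#' (complete case) with a count recorded; tests whose preconditions fail
#' (too few pairs, fewer than two classes or participants) are reported as
#' skipped rather than failing the battery.
#'
#' @param tab a measure table ([as_measure_table()]).
#' @param alpha family-wise error level for the Holm correction.
#' @param df_method denominator-df approximation for the LMMs.
#' @return an object of class `stat_report`: list with `tests` (tibble:
#'   `test`, `type`, `statistic`, `p`, `n`, `skipped`, `reason`, plus Holm
#'   columns `threshold`, `reject`), `lmm` (list of `complexity_lmm`),
#'   `outliers` (tibble), `alpha`.
#' @export
run_paper_tests <- function(tab, alpha = 0.05,
                            df_method = c("Satterthwaite", "Kenward-Roger")) {
  df_method <- match.arg(df_method)
  tab <- as_measure_table(tab)
  if (nrow(tab) == 0L) stop("measure table is empty", call. = FALSE)
  # a table missing one state still runs: the affected tests come back
  # flagged as skipped rather than aborting the battery
  sed_pcist <- sedation_means(tab, "pcist")
  sed_lzc <- sedation_means(tab, "lzc")
  wake_pcist <- wake_values(tab, "pcist", "wake_ec")
  lzc_eo <- wake_values(tab, "lzc", "wake_eo")
  lzc_ec <- wake_values(tab, "lzc", "wake_ec")

  run_wilcoxon <- function(a, b) {
    pr <- paired_values(a, b)
    res <- tryCatch(wilcoxon_z(pr$x, pr$y), error = function(e) e)
    if (inherits(res, "error")) {
      list(statistic = NA_real_, p = NA_real_, n = pr$n, skipped = TRUE,
           reason = conditionMessage(res))
    } else {
      if (pr$dropped > 0) {
        warning(sprintf("%d unpaired participant(s) dropped", pr$dropped),
                call. = FALSE)
      }
      list(statistic = res$Z, p = res$p, n = res$n_pairs, skipped = FALSE,
           reason = NA_character_)
    }
  }
  run_lmm <- function(measure) {
    sed <- sedation_rows(tab)
    sed <- sed[sed$measure == measure & !is.na(sed$experience_class), , drop = FALSE]
    res <- tryCatch(fit_lmm(sed, df_method = df_method), error = function(e) e)
    if (inherits(res, "error")) {
      list(fit = NULL, statistic = NA_real_, p = NA_real_, n = nrow(sed),
           skipped = TRUE, reason = conditionMessage(res))
    } else {
      list(fit = res, statistic = res$F, p = res$p, n = nrow(sed),
           skipped = FALSE, reason = NA_character_)
    }
  }

  w <- list(
    pcist_w_vs_sed = run_wilcoxon(wake_pcist, sed_pcist),
    lzc_wo_vs_wc   = run_wilcoxon(lzc_eo, lzc_ec),
    lzc_wo_vs_sed  = run_wilcoxon(lzc_eo, sed_lzc),
    lzc_wc_vs_sed  = run_wilcoxon(lzc_ec, sed_lzc)
  )
  l <- list(
    lmm_pcist_class = run_lmm("pcist"),
    lmm_lzc_class   = run_lmm("lzc")
  )
  all_tests <- c(w, l)
  tests <- tibble::tibble(
    test = names(all_tests),
    type = c(rep("wilcoxon", 4), rep("lmm", 2)),
    statistic = unname(vapply(all_tests, function(z) z$statistic, numeric(1))),
    p = unname(vapply(all_tests, function(z) z$p, numeric(1))),
    n = unname(vapply(all_tests, function(z) as.double(z$n), numeric(1))),
    skipped = unname(vapply(all_tests, function(z) z$skipped, logical(1))),
    reason = unname(vapply(all_tests, function(z) z$reason, character(1)))
  )
  hb <- holm(tibble::tibble(test = tests$test, p = tests$p), alpha = alpha)
  tests$threshold <- hb$threshold
  tests$reject <- hb$reject

  distros <- list(
    pcist_wake = wake_pcist,
    pcist_sedation = sedation_rows(tab)$value[sedation_rows(tab)$measure == "pcist"],
    lzc_wake_eo = lzc_eo,
    lzc_wake_ec = lzc_ec,
    lzc_sedation = sedation_rows(tab)$value[sedation_rows(tab)$measure == "lzc"]
  )
  outliers <- dplyr::bind_rows(lapply(names(distros), function(nm) {
    v <- as.numeric(distros[[nm]])
    if (length(v) < 4L) return(NULL)
    tibble::tibble(distribution = nm, value = v, flag = iqr_outliers(v))
  }))

  structure(
    list(tests = tests,
         lmm = list(pcist = l$lmm_pcist_class$fit, lzc = l$lmm_lzc_class$fit),
         outliers = outliers, alpha = alpha),
    class = "stat_report"
  )
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %d tests, Holm at alpha = %g\n", nrow(x$tests), x$alpha))
  print(as.data.frame(x$tests[, c("test", "statistic", "p", "reject", "skipped")]),
        digits = 4)
  if (nrow(x$outliers)) {
    nfl <- sum(x$outliers$flag)
    cat(sprintf(" outlier flags: %d of %d values\n", nfl, nrow(x$outliers)))
  }
  invisible(x)
}

#' @rdname run_paper_tests
#' @param x a `stat_report`.
#' @param ... unused.
#' @export
tidy.stat_report <- function(x, ...) x$tests

#' @rdname run_paper_tests
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x$tests),
                 n_rejected = sum(x$tests$reject, na.rm = TRUE),
                 n_skipped = sum(x$tests$skipped),
                 n_outlier_flags = sum(x$outliers$flag),
                 alpha = x$alpha)
}
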