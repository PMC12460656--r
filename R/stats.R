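#' Random-intercept linear mixed model for a consciousness measure
#'
#' Fits, by REML, `value ~ experience_class + (1 | participant_id)` on the
#' sedation rows of a measure table: the measure as dependent variable, the
#' three-level experience classification as a categorical fixed effect
#' (reference level `no_experience`), and a per-participant random
#' intercept. Reports the Type-III F test for the class effect with
#' Satterthwaite denominator degrees of freedom (configurable) and the
#' estimated marginal means per class (population level, random effects at
#' zero).
#'
#' @param data a data frame with columns `value`, the fixed-effect column,
#'   and the grouping column (typically a measure table filtered to one
#'   measure under sedation).
#' @param fixed name of the categorical fixed-effect column
#'   (default `"experience_class"`).
#' @param group name of the random-intercept grouping column
#'   (default `"participant_id"`).
#' @param response name of the dependent-variable column (default `"value"`).
#' @param df_method denominator-df approximation: `"Satterthwaite"` or
#'   `"Kenward-Roger"`.
#' @return an object of class `complexity_lmm`: list with the `lmerMod`
#'   `fit`, `F`, `ndf`, `ddf`, `p`, `emms` (tibble), `variance_components`,
#'   and `singular` (TRUE when the random-intercept variance collapsed
#'   to 0 — reported as a flag, not an error).
#' @export
fit_lmm <- function(data, fixed = "experience_class", group = "participant_id",
                    response = "value",
                    df_method = c("Satterthwaite", "Kenward-Roger")) {
  df_method <- match.arg(df_method)
  d <- as.data.frame(data)
  if (!all(c(response, fixed, group) %in% names(d))) {
    stop("`data` must contain the response, fixed-effect and grouping columns",
         call. = FALSE)
  }
  vals <- unique(as.character(d[[fixed]]))
  lv <- c(intersect(class_levels(), vals), setdiff(sort(vals), class_levels()))
  d[[fixed]] <- factor(as.character(d[[fixed]]), levels = lv)
  if ("no_experience" %in% lv) {
    d[[fixed]] <- stats::relevel(d[[fixed]], ref = "no_experience")
  }
  if (length(unique(d[[group]])) < 2L) {
    stop("need >= 2 participants", call. = FALSE)
  }
  single_class <- nlevels(d[[fixed]]) < 2L
  # one observed class: no F test is possible, but the intercept-only fit
  # still yields the class EMM
  fml <- if (single_class) {
    stats::as.formula(sprintf("%s ~ 1 + (1 | %s)", response, group))
  } else {
    stats::as.formula(sprintf("%s ~ %s + (1 | %s)", response, fixed, group))
  }
  fit <- suppressMessages(lmerTest::lmer(fml, data = d, REML = TRUE))
  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  if (single_class) {
    cf <- summary(fit)$coefficients
    Fv <- NA_real_; ndf <- NA_real_; ddf <- NA_real_; pv <- NA_real_
    emms <- tibble::tibble(class = levels(d[[fixed]]),
                           emmean = cf[1L, "Estimate"],
                           se = cf[1L, "Std. Error"], df = cf[1L, "df"])
  } else {
    an <- stats::anova(fit, type = 3, ddf = df_method)
    Fv <- an[fixed, "F value"]; ndf <- an[fixed, "NumDF"]
    ddf <- an[fixed, "DenDF"]; pv <- an[fixed, "Pr(>F)"]
    emm_tab <- summary(emmeans::emmeans(fit, stats::as.formula(paste0("~", fixed)),
                                        lmer.df = tolower(df_method)))
    emms <- tibble::tibble(class = as.character(emm_tab[[fixed]]),
                           emmean = emm_tab$emmean, se = emm_tab$SE,
                           df = emm_tab$df)
  }
  structure(
    list(fit = fit,
         F = Fv,
         ndf = ndf,
         ddf = ddf,
         p = pv,
         emms = emms,
         variance_components = c(
           sigma2_u = vc$vcov[vc$grp == group][1L],
           sigma2_eps = vc$vcov[vc$grp == "Residual"][1L]),
         singular = singular,
         df_method = df_method),
    class = "complexity_lmm"
  )
}

#' @export
print.complexity_lmm <- function(x, ...) {
  cat(sprintf("<complexity_lmm> Type-III F(%.0f, %.1f) = %.3f, p = %.4g%s\n",
              x$ndf, x$ddf, x$F, x$p,
              if (x$singular) " [singular fit]" else ""))
  print(x$emms)
  invisible(x)
}

#' Estimated marginal means of a fitted mixed model
#'
#' Per-class marginal predictions at the population level (random effects
#' at zero) with standard errors; for a balanced design these equal the raw
#' class means.
#'
#' @param result a `complexity_lmm` from [fit_lmm()].
#' @return tibble with columns `class`, `emmean`, `se`, `df`.
#' @export
emm <- function(result) {
  if (!inherits(result, "complexity_lmm")) {
    stop("`result` must be a complexity_lmm", call. = FALSE)
  }
  result$emms
}

#' @rdname fit_lmm
#' @param x a `complexity_lmm`.
#' @param ... unused.
#' @export
tidy.complexity_lmm <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std.error = cf[, "Std. Error"], df = cf[, "df"],
                 statistic = cf[, "t value"], p.value = cf[, "Pr(>|t|)"])
}

#' @rdname fit_lmm
#' @export
glance.complexity_lmm <- function(x, ...) {
  tibble::tibble(F = x$F, ndf = x$ndf, ddf = x$ddf, p.value = x$p,
                 sigma2_u = x$variance_components[["sigma2_u"]],
                 sigma2_eps = x$variance_components[["sigma2_eps"]],
                 singular = x$singular)
}

#' Matched-pairs Wilcoxon signed-rank test (normal approximation)
#'
#' Computes differences `d = y - x`, drops zeros, ranks `|d|` with midranks
#' for ties, and forms the positive-rank sum `T+`. The signed statistic is
#' `Z = (T+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie_correction)` with
#' `tie_correction = sum(t^3 - t)/48` over tie groups and no continuity
#' correction; the two-sided p-value comes from the normal law. For a fully
#' concordant set of 20 pairs this gives `Z = -3.92`.
#'
#' @param x,y paired value vectors of equal length (`n >= 5` non-zero
#'   differences required for the approximation).
#' @return one-row tibble of class `wilcoxon_result`: `Z`, `p`, `n_pairs`,
#'   `t_plus`.
#' @export
wilcoxon_z <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- stats::complete.cases(x, y)
  d <- y[keep] - x[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero: test undefined", call. = FALSE)
  if (n < 5L) stop("need >= 5 non-zero pairs for the normal approximation", call. = FALSE)
  r <- rank(abs(d))
  t_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / 48
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_corr)
  z <- (t_plus - mu) / sigma
  out <- tibble::tibble(Z = z, p = 2 * pnorm(-abs(z)), n_pairs = n,
                        t_plus = t_plus)
  class(out) <- c("wilcoxon_result", class(out))
  out
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts the p-values ascending and compares the i-th smallest against
#' `alpha / (m - i + 1)`, stopping at the first failure; every test before
#' the stop is rejected.
#'
#' @param pvals named numeric vector of p-values in `[0, 1]` (or a data
#'   frame with columns `test` and `p`).
#' @param alpha family-wise error level.
#' @return tibble with columns `test`, `p`, `rank`, `threshold`, `reject`,
#'   in the original test order.
#' @examples
#' holm(c(a = 0.001, b = 0.004, c = 0.02, d = 0.03, e = 0.2, f = 0.9))
#' @export
holm <- function(pvals, alpha = 0.05) {
  if (is.data.frame(pvals)) {
    nm <- as.character(pvals$test); p <- as.numeric(pvals$p)
  } else {
    p <- as.numeric(pvals)
    nm <- names(pvals)
    if (is.null(nm)) nm <- paste0("test", seq_along(p))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  thr <- alpha / (m - seq_len(m) + 1)
  rej_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (!is.na(p[ord[i]]) && p[ord[i]] < thr[i]) rej_sorted[i] <- TRUE else break
  }
  out <- tibble::tibble(test = nm, p = p,
                        rank = match(seq_along(p), ord),
                        threshold = thr[match(seq_along(p), ord)],
                        reject = rej_sorted[match(seq_along(p), ord)])
  out
}

#' Flag outliers by the 1.5 IQR fence
#'
#' Flags values above `Q3 + 1.5 IQR` or below `Q1 - 1.5 IQR`, with
#' quartiles computed by linear interpolation between order statistics
#' (quantile type 7); this convention is pinned because flags can differ
#' across quartile definitions.
#'
#' @param values numeric vector (`n >= 4`).
#' @return logical vector of flags.
#' @examples
#' iqr_outliers(c(1, 2, 3, 4, 100))  # only 100 flagged
#' @export
iqr_outliers <- function(values) {
  if (length(values) < 4L) stop("need >= 4 values", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values > q[2] + 1.5 * iqr | values < q[1] - 1.5 * iqr
}
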