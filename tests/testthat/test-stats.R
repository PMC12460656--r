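test_that("fully concordant pair sets reproduce the closed-form Z scores", {
  # T+ = 0, mean n(n+1)/4, sd sqrt(n(n+1)(2n+1)/24)
  for (case in list(c(20, -3.92), c(17, -3.62), c(15, -3.41))) {
    n <- case[1]
    x <- seq_len(n) + 10                         # wake values
    y <- x - seq(0.5, 2, length.out = n)         # all lower, untied |d|
    res <- wilcoxon_z(x, y)
    expect_equal(round(res$Z, 2), case[2])
    expect_equal(res$t_plus, 0)
    expect_equal(res$n_pairs, n)
    expect_lt(res$p, 0.001)
  }
})

test_that("the signed-rank statistic is antisymmetric and respects ties", {
  set.seed(81)
  x <- rnorm(12); y <- x + rnorm(12)
  expect_equal(wilcoxon_z(x, y)$Z, -wilcoxon_z(y, x)$Z)
  # midranks with tie correction: |d| = (1,1,2,2,2) all negative
  xt <- c(1, 1, 2, 2, 2, 5); yt <- xt - c(1, 1, 2, 2, 2, 0.5)
  res <- wilcoxon_z(xt, yt)
  n <- 6; mu <- n * (n + 1) / 4
  ties <- c(2, 3, 1)
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48)
  expect_equal(res$Z, (0 - mu) / sigma)
})

test_that("zero differences are dropped and degenerate input raises", {
  x <- c(1, 2, 3, 4, 5, 6, 7)
  y <- c(1, 2, 3, 5, 6, 7, 8)  # three zero differences -> 4 pairs, below minimum
  expect_error(wilcoxon_z(x, y), ">= 5")
  expect_error(wilcoxon_z(x, x), "all paired differences are zero")
  expect_error(wilcoxon_z(1:3, 1:4), "equal length")
  # a single nonzero difference among many determines the sign
  y2 <- x; y2[3] <- x[3] + 2
  x2 <- c(x, 10:14); y2 <- c(y2, 10:14 - 1)
  res <- wilcoxon_z(x2, y2)
  expect_lt(res$Z, 0)  # negatives dominate
})

test_that("Holm step-down matches the hand-worked example", {
  p <- c(a = 0.001, b = 0.004, c = 0.02, d = 0.03, e = 0.2, f = 0.9)
  out <- holm(p, alpha = 0.05)
  # 0.001 < 0.05/6, 0.004 < 0.05/5, then 0.02 >= 0.05/4 = 0.0125: stop
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$threshold[out$test == "a"], 0.05 / 6)
  expect_equal(out$threshold[out$test == "c"], 0.05 / 4)
  expect_true(holm(c(t1 = 0.04))$reject)
  expect_false(any(holm(rep(1, 4))$reject))
})

test_that("Holm agrees with the adjusted-p oracle and is monotone", {
  set.seed(91)
  for (i in 1:200) {
    m <- sample(2:8, 1)
    p <- round(runif(m), 3)
    mine <- holm(p, alpha = 0.05)$reject
    oracle <- stats::p.adjust(p, method = "holm") < 0.05
    expect_equal(mine, unname(oracle))
  }
  # lowering one p never un-rejects another test
  p0 <- c(0.001, 0.02, 0.03, 0.2)
  base <- holm(p0)$reject
  p1 <- p0; p1[4] <- 0.0005
  after <- holm(p1)$reject
  expect_true(all(after[base]))
})

test_that("IQR fences flag exactly the extreme points", {
  expect_equal(iqr_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(rep(3, 6))))
  expect_false(any(iqr_outliers(c(-2, -1, 0, 1, 2))))
  expect_error(iqr_outliers(1:3), ">= 4")
})

test_that("noiseless group structure is recovered exactly by the mixed model", {
  set.seed(71)
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), each = 3),
    experience_class = rep(c("no_experience", "no_information", "experience"), 6),
    value = rep(c(10, 20, 30), 6) + rnorm(18, 0, 1e-6)
  )
  fit <- suppressMessages(fit_lmm(d))
  em <- emm(fit)
  expect_equal(em$emmean[em$class == "no_experience"], 10, tolerance = 1e-3)
  expect_equal(em$emmean[em$class == "no_information"], 20, tolerance = 1e-3)
  expect_equal(em$emmean[em$class == "experience"], 30, tolerance = 1e-3)
  expect_gte(fit$F, 0)
  # at machine-precision residuals the Satterthwaite denominator df
  # degenerates numerically, so the p assertion uses a small but
  # representable residual scale
  d$value <- rep(c(10, 20, 30), 6) + rnorm(18, 0, 1e-3)
  fit2 <- suppressMessages(fit_lmm(d))
  expect_lt(fit2$p, 1e-6)
})

test_that("with no participant variance the F test collapses to one-way ANOVA", {
  set.seed(101)
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:10), each = 3),
    experience_class = sample(rep(c("no_experience", "no_information",
                                    "experience"), 10)),
    value = rnorm(30, 5, 1)
  )
  d$value <- d$value + c(0, 0.5, 1)[match(d$experience_class,
                                          c("no_experience", "no_information",
                                            "experience"))]
  fit <- suppressMessages(fit_lmm(d))
  expect_true(fit$singular)  # random-intercept variance on the boundary
  a <- stats::anova(stats::aov(value ~ experience_class, data = d))
  expect_equal(fit$F, a$`F value`[1], tolerance = 1e-6)
  expect_equal(fit$ddf, a$Df[2], tolerance = 1e-3)
})

test_that("EMMs equal raw class means in a balanced design", {
  set.seed(111)
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:8), each = 3),
    experience_class = rep(c("no_experience", "no_information", "experience"), 8),
    value = rnorm(24, 10, 2)
  )
  fit <- suppressMessages(fit_lmm(d))
  em <- emm(fit)
  raw <- tapply(d$value, d$experience_class, mean)
  for (cl in names(raw)) {
    expect_equal(em$emmean[em$class == cl], unname(raw[cl]), tolerance = 1e-9)
  }
})

test_that("EMMs down-weight a dominant participant in unbalanced data", {
  set.seed(121)
  # participant P01 contributes most of one class and sits far above the rest
  d <- tibble::tibble(
    participant_id = c(rep("P01", 8), sprintf("P%02d", 2:7)),
    experience_class = c(rep("experience", 8),
                         rep(c("experience", "no_experience"), 3)),
    value = c(rnorm(8, 30, 1), rnorm(3, 10, 1), rnorm(3, 8, 1))
  )
  fit <- suppressMessages(fit_lmm(d))
  em <- emm(fit)
  raw <- mean(d$value[d$experience_class == "experience"])
  model_em <- em$emmean[em$class == "experience"]
  # raw mean is dragged toward P01; the model pulls back toward the others
  expect_lt(model_em, raw)
})

test_that("single observed class yields the intercept as its EMM", {
  set.seed(131)
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:5), each = 2),
    experience_class = "experience",
    value = rnorm(10, 7, 1)
  )
  fit <- suppressMessages(fit_lmm(d))
  expect_true(is.na(fit$F))
  em <- emm(fit)
  expect_equal(nrow(em), 1L)
  expect_equal(em$emmean, unname(lme4::fixef(fit$fit)[1]))
})

test_that("broom-style tidiers expose coefficients and fit summary", {
  set.seed(141)
  d <- tibble::tibble(
    participant_id = rep(sprintf("P%02d", 1:6), each = 3),
    experience_class = rep(c("no_experience", "no_information", "experience"), 6),
    value = rnorm(18)
  )
  fit <- suppressMessages(fit_lmm(d))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in% names(td)))
  expect_equal(nrow(td), 3L)
  gl <- glance(fit)
  expect_true(all(c("F", "p.value", "sigma2_u", "sigma2_eps") %in% names(gl)))
  expect_gte(gl$sigma2_eps, 0)
})
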