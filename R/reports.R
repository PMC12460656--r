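#' Category vocabularies for awakening reports
#'
#' Q1 ("What did you experience?") is categorized by the level of detail in
#' the answer: `nothing` (positively reported no experience), `no_info` (no
#' or incomprehensible answer), `white` (remembers something but not what),
#' `vague` (isolated feelings, colors, faces), `vivid` (scenes and stories).
#' Q2 ("Did you experience anything?") is `no`, `no_info`, `maybe`, or
#' `yes`. The overall experience classification has three classes:
#' `experience`, `no_information`, `no_experience`.
#'
#' @name report-vocabulary
#' @keywords internal
NULL

q1_levels <- function() c("nothing", "no_info", "white", "vague", "vivid")
q2_levels <- function() c("no", "no_info", "maybe", "yes")
class_levels <- function() c("experience", "no_information", "no_experience")

#' Experience-classification rule
#'
#' The rule mapping each (Q1, Q2) combination to one of the three experience
#' classes is a plain 5 x 4 character matrix (rows = Q1 categories, columns
#' = Q2 categories), so alternative readings of the scheme can be swapped
#' in. The default rule applies, in order:
#'
#' 1. Q1 gives positive detail (`white`, `vague`, `vivid`) -> `experience`
#'    (positive detail dominates, even over a conflicting Q2 = `no`);
#' 2. otherwise Q2 = `yes` -> `experience`;
#' 3. otherwise Q1 = `nothing` or Q2 = `no` -> `no_experience`;
#' 4. otherwise -> `no_information` (an uncertain `maybe` with an
#'    uninformative Q1 is treated as not informative).
#'
#' @param table optional 5 x 4 character matrix over the class vocabulary,
#'   with dimnames matching the Q1/Q2 vocabularies, replacing the default.
#' @return a classification rule: a class-valued matrix of class
#'   `classification_rule`.
#' @examples
#' classification_rule()["vivid", "yes"]
#' @export
classification_rule <- function(table = NULL) {
  q1 <- q1_levels(); q2 <- q2_levels()
  if (is.null(table)) {
    tab <- matrix("", length(q1), length(q2), dimnames = list(q1, q2))
    for (i in q1) for (j in q2) {
      tab[i, j] <-
        if (i %in% c("white", "vague", "vivid")) "experience"
        else if (j == "yes") "experience"
        else if (i == "nothing" || j == "no") "no_experience"
        else "no_information"
    }
  } else {
    tab <- table
    if (!is.matrix(tab) || !identical(rownames(tab), q1) ||
        !identical(colnames(tab), q2) || !all(tab %in% class_levels())) {
      stop("`table` must be a 5x4 class matrix with Q1 rows and Q2 columns",
           call. = FALSE)
    }
  }
  structure(tab, class = c("classification_rule", "matrix"))
}

#' Classify one awakening report into an experience class
#'
#' @param q1 Q1 category (see [classification_rule()] for the scheme).
#' @param q2 Q2 category.
#' @param rule a [classification_rule()].
#' @return the experience class as a character scalar (vectorized over
#'   `q1`/`q2`).
#' @examples
#' classify_awakening("vivid", "yes")    # "experience"
#' classify_awakening("no_info", "no")   # "no_experience"
#' @export
classify_awakening <- function(q1, q2, rule = classification_rule()) {
  q1 <- as.character(q1); q2 <- as.character(q2)
  if (length(q1) != length(q2)) stop("`q1` and `q2` lengths differ", call. = FALSE)
  bad1 <- setdiff(unique(q1), q1_levels())
  bad2 <- setdiff(unique(q2), q2_levels())
  if (length(bad1)) stop("unknown Q1 category: ", paste(bad1, collapse = ", "), call. = FALSE)
  if (length(bad2)) stop("unknown Q2 category: ", paste(bad2, collapse = ", "), call. = FALSE)
  vapply(seq_along(q1), function(i) rule[q1[i], q2[i]], character(1))
}

#' Add the experience class to a table of awakening reports
#'
#' @param reports a data frame with columns `q1` and `q2`.
#' @param rule a [classification_rule()].
#' @return the input as a tibble with an `experience_class` factor column
#'   appended.
#' @export
classify_reports <- function(reports, rule = classification_rule()) {
  if (!all(c("q1", "q2") %in% names(reports))) {
    stop("`reports` must have columns q1 and q2", call. = FALSE)
  }
  out <- tibble::as_tibble(reports)
  out$experience_class <- factor(
    classify_awakening(out$q1, out$q2, rule = rule),
    levels = class_levels()
  )
  out
}

#' Tabulate report categories and experience classes
#'
#' Exact counts per Q1 category, per Q2 category, and per experience class,
#' each as a tibble; the grand total of each equals the number of
#' awakenings.
#'
#' @param reports a data frame with columns `q1` and `q2`.
#' @param rule a [classification_rule()].
#' @return a list of class `report_tabulation` with tibbles `q1`, `q2`,
#'   `class`, and the scalar `n_awakenings`.
#' @examples
#' tab <- tabulate_reports(gen_reports(seed = 1))
#' tab$class
#' @export
tabulate_reports <- function(reports, rule = classification_rule()) {
  if (nrow(reports) == 0L) stop("`reports` is empty", call. = FALSE)
  cls <- classify_reports(reports, rule = rule)
  count_lv <- function(x, lv) {
    tibble::tibble(category = lv,
                   n = as.integer(table(factor(x, levels = lv))[lv]))
  }
  structure(
    list(
      q1 = count_lv(as.character(cls$q1), q1_levels()),
      q2 = count_lv(as.character(cls$q2), q2_levels()),
      class = count_lv(as.character(cls$experience_class), class_levels()),
      n_awakenings = nrow(cls)
    ),
    class = "report_tabulation"
  )
}

#' @export
print.report_tabulation <- function(x, ...) {
  cat(sprintf("<report_tabulation> %d awakenings\n", x$n_awakenings))
  cat(" Q1:    ", paste(sprintf("%s=%d", x$q1$category, x$q1$n), collapse = " "), "\n")
  cat(" Q2:    ", paste(sprintf("%s=%d", x$q2$category, x$q2$n), collapse = " "), "\n")
  cat(" class: ", paste(sprintf("%s=%d", x$class$category, x$class$n), collapse = " "), "\n")
  invisible(x)
}
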