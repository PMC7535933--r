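#' Two-sample t-test (pooled-variance Student by default)
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param variant `"student"` (pooled variance, the reporting default) or
#'   `"welch"`.
#' @return A `test_result`: tibble with `test`, `statistic`, `df`,
#'   `p_value`, `n_a`, `n_b`, `degenerate`.
#' @export
ttest_two_sample <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  degenerate <- FALSE
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_test_result(
        test = paste0("t_", variant), statistic = 0,
        df = length(a) + length(b) - 2, p_value = 1,
        n_a = length(a), n_b = length(b), degenerate = TRUE
      ))
    }
    degenerate <- TRUE
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  new_test_result(
    test = paste0("t_", variant),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_a = length(a), n_b = length(b),
    degenerate = degenerate
  )
}

#' Chi-square test on a 2x2 contingency table
#'
#' Uncorrected by default: on integer counts the statistic equals the
#' closed form N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with df = 1.
#'
#' @param table 2x2 non-negative count matrix.
#' @param continuity `"none"` (default) or `"yates"`.
#' @return A `test_result` tibble.
#' @export
chisq_2x2 <- function(table, continuity = c("none", "yates")) {
  continuity <- match.arg(continuity)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square undefined: zero marginal", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(table, correct = (continuity == "yates"))
  )
  new_test_result(
    test = paste0("chisq_", continuity),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_a = sum(table[1, ]), n_b = sum(table[2, ]),
    degenerate = FALSE
  )
}

#' One-way ANOVA
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @return A `test_result` tibble (`df` holds the between-groups df; the
#'   within-groups df is in `df2`).
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  lens <- lengths(groups)
  stopifnot(all(lens >= 2))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lens))
  degenerate <- all(vapply(groups, var, numeric(1)) == 0)
  if (degenerate && length(unique(vapply(groups, mean, numeric(1)))) == 1) {
    return(new_test_result(
      test = "anova_oneway", statistic = 0,
      df = length(groups) - 1, p_value = 1,
      n_a = length(y), n_b = NA_integer_,
      degenerate = TRUE, df2 = length(y) - length(groups)
    ))
  }
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  new_test_result(
    test = "anova_oneway",
    statistic = s[["F value"]][1],
    df = s[["Df"]][1],
    p_value = s[["Pr(>F)"]][1],
    n_a = length(y), n_b = NA_integer_,
    degenerate = degenerate,
    df2 = s[["Df"]][2]
  )
}

new_test_result <- function(test, statistic, df, p_value, n_a, n_b,
                            degenerate = FALSE, df2 = NA_real_) {
  out <- tibble(
    test = test, statistic = statistic, df = df, df2 = df2,
    p_value = p_value, n_a = n_a, n_b = n_b, degenerate = degenerate
  )
  class(out) <- c("test_result", class(out))
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, df = %s%s, p = %.4g%s\n",
              x$test, x$statistic, format(x$df),
              if (is.na(x$df2)) "" else paste0("/", format(x$df2)),
              x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Printed percentage (one decimal, round half up)
#'
#' @param count,total Non-negative counts.
#' @return Percentage rounded to one decimal, half up (17/28 -> 60.7).
#' @export
percent_of <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, 1)
}

#' Cohort summary report
#'
#' Builds per-cell and per-condition tables from an analysed cohort:
#' trajectory-mode percentages (one decimal, round half up), a 2x2
#' condition-by-mode contingency with its uncorrected chi-square (Fisher
#' exact p attached alongside, since small tables make the choice of test
#' consequential), and per-phase distance/speed tests. Optionally writes
#' the per-cell CSV and a JSON report carrying all parameters and seeds.
#'
#' @param cells Tibble with one row per cell; must contain `mode`, may
#'   contain `condition`, `latency_hr`, `loss_delay_min`, per-phase
#'   summaries.
#' @param out_dir Optional output directory for `cells.csv` and
#'   `report.json`.
#' @param params Optional list of parameters/seeds recorded in the JSON.
#' @return A `cohort_summary` list: `cells`, `percentages` (tibble:
#'   `condition`, `mode`, `count`, `total`, `percent`), `contingency`
#'   (matrix or `NULL`), `tests` (tibble of test results).
#' @export
cohort_report <- function(cells, out_dir = NULL, params = list()) {
  cells <- tibble::as_tibble(cells)
  if (!nrow(cells)) {
    out <- list(cells = cells,
                percentages = tibble(condition = character(),
                                     mode = character(), count = integer(),
                                     total = integer(), percent = numeric()),
                contingency = NULL,
                tests = tibble())
    class(out) <- "cohort_summary"
    return(out)
  }
  if (!"condition" %in% names(cells)) cells$condition <- "all"
  pct <- cells |>
    dplyr::count(.data$condition, .data$mode, name = "count") |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(total = sum(.data$count),
                  percent = percent_of(.data$count, .data$total)) |>
    dplyr::ungroup()

  tests <- list()
  contingency <- NULL
  conds <- unique(cells$condition)
  modes <- intersect(c("direct", "reversal"), unique(cells$mode))
  if (length(conds) == 2 && length(modes) == 2) {
    contingency <- table(factor(cells$condition, conds),
                         factor(cells$mode, modes))
    contingency <- matrix(as.integer(contingency), 2, 2,
                          dimnames = dimnames(contingency))
    if (all(rowSums(contingency) > 0) && all(colSums(contingency) > 0)) {
      chi <- chisq_2x2(contingency)
      tests[[length(tests) + 1L]] <- chi
      fish <- stats::fisher.test(contingency)
      tests[[length(tests) + 1L]] <- new_test_result(
        test = "fisher_exact", statistic = NA_real_, df = NA_real_,
        p_value = fish$p.value,
        n_a = sum(contingency[1, ]), n_b = sum(contingency[2, ])
      )
    }
  }
  tests <- if (length(tests)) dplyr::bind_rows(tests) else tibble()

  out <- list(cells = cells, percentages = pct,
              contingency = contingency, tests = tests)
  class(out) <- "cohort_summary"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cells, file.path(out_dir, "cells.csv"))
    jsonlite::write_json(
      list(
        params = params,
        percentages = pct,
        contingency = if (is.null(contingency)) NULL else
          as.data.frame.table(contingency),
        tests = tests
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cells\n", nrow(x$cells)))
  if (nrow(x$percentages)) print(x$percentages)
  if (nrow(x$tests)) print(as.data.frame(x$tests))
  invisible(x)
}
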