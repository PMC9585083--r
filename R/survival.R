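#' NOTCH-pathway activation score
#'
#' The arithmetic mean of the four canonical NOTCH target genes HES1, HES2,
#' HEY1 and HEY2 per patient, on whatever (log-scale) normalized expression
#' the cohort table carries.
#'
#' @param cohort Cohort tibble with columns `hes1`, `hes2`, `hey1`, `hey2`
#'   (and `patient_id` for error reporting).
#' @return The cohort tibble with a `notch_score` column appended.
#' @export
notch_score <- function(cohort) {
  genes <- c("hes1", "hes2", "hey1", "hey2")
  miss <- setdiff(genes, names(cohort))
  if (length(miss)) {
    abort(sprintf("Cohort is missing score gene column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  for (g in genes) {
    bad <- which(!is.finite(cohort[[g]]))
    if (length(bad)) {
      who <- if ("patient_id" %in% names(cohort)) {
        cohort$patient_id[bad[1]]
      } else {
        paste("row", bad[1])
      }
      abort(sprintf("Missing %s expression for patient %s.", toupper(g), who))
    }
  }
  cohort %>%
    mutate(notch_score = (.data$hes1 + .data$hes2 + .data$hey1 + .data$hey2) / 4)
}

#' Dichotomize an expression vector
#'
#' Labels values `high` when strictly above the threshold and `low`
#' otherwise; values exactly equal to the threshold are `low` (strict `>`).
#' The threshold may be the literal string `"median"`, in which case the
#' sample median is used and recorded.
#'
#' @param values Numeric vector (length >= 2).
#' @param threshold A number, or `"median"`.
#' @return Factor with levels `low`, `high`; the resolved threshold is
#'   attached as attribute `"threshold"`.
#' @export
dichotomize <- function(values, threshold = "median") {
  if (!is.numeric(values) || length(values) < 2L) {
    abort("`values` must be a numeric vector of length >= 2.")
  }
  thr <- if (identical(threshold, "median")) {
    median(values)
  } else {
    check_scalar_number(threshold, "threshold")
  }
  out <- factor(if_else(values > thr, "high", "low"),
                levels = c("low", "high"))
  attr(out, "threshold") <- thr
  out
}

#' Stratify a cohort into the four NOTCH-score x CIITA groups
#'
#' Crosses a NOTCH-activation dichotomy (score from [notch_score()], high =
#' strictly above threshold) with a CIITA dichotomy. Thresholds default to
#' this cohort's medians but can be frozen numbers derived from a reference
#' cohort and re-applied to a second cohort, in which case the labels depend
#' only on the new cohort's values and the frozen thresholds.
#'
#' @param cohort Cohort tibble (`hes1`..`hey2`, `ciita`, ...).
#' @param notch_threshold `"median"` or a frozen numeric threshold for the
#'   NOTCH score.
#' @param ciita_threshold `"median"` or a frozen numeric threshold for CIITA
#'   expression (e.g. 14.9 on the reference cohort's log scale).
#' @return The cohort tibble with `notch_score`, `notch_group`,
#'   `ciita_group` and `four_group` columns; resolved thresholds are
#'   attached as attribute `"thresholds"` (retrieve with
#'   [strata_thresholds()]).
#' @export
stratify_four_groups <- function(cohort, notch_threshold = "median",
                                 ciita_threshold = "median") {
  if (!"ciita" %in% names(cohort)) abort("Cohort needs a `ciita` column.")
  out <- if ("notch_score" %in% names(cohort)) cohort else notch_score(cohort)
  ng <- dichotomize(out$notch_score, notch_threshold)
  cg <- dichotomize(out$ciita, ciita_threshold)
  out <- out %>%
    mutate(notch_group = ng,
           ciita_group = cg,
           four_group = factor(paste0("notch_", ng, ".ciita_", cg),
                               levels = c("notch_low.ciita_high",
                                          "notch_low.ciita_low",
                                          "notch_high.ciita_high",
                                          "notch_high.ciita_low")))
  attr(out, "thresholds") <- list(notch = attr(ng, "threshold"),
                                  ciita = attr(cg, "threshold"))
  out
}

#' Thresholds recorded by a stratification
#'
#' @param x A tibble returned by [stratify_four_groups()].
#' @return Named list with `notch` and `ciita` thresholds.
#' @export
strata_thresholds <- function(x) {
  thr <- attr(x, "thresholds")
  if (is.null(thr)) abort("`x` carries no recorded thresholds.")
  thr
}

km_curve_one <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time)
  n_risk <- vapply(ut, function(t0) sum(time >= t0), numeric(1))
  n_event <- vapply(ut, function(t0) sum(time == t0 & event == 1L), numeric(1))
  n_censor <- vapply(ut, function(t0) sum(time == t0 & event == 0L), numeric(1))
  tibble(time = ut,
         n_risk = as.integer(n_risk),
         n_event = as.integer(n_event),
         n_censor = as.integer(n_censor),
         survival = cumprod(1 - n_event / n_risk))
}

#' Kaplan-Meier product-limit estimator
#'
#' The standard product-limit estimate, implemented from first principles:
#' at each distinct event time `t_i`, the survival curve drops by the factor
#' `(1 - d_i / n_i)` where `d_i` is the number of events and `n_i` the
#' number at risk (subjects censored at `t_i` still count as at risk there).
#'
#' @param data Data frame of subjects.
#' @param time Name of the positive time column.
#' @param event Name of the event-indicator column (1 = event, 0 =
#'   censored).
#' @param group Optional name of a grouping column; one curve per group.
#' @return A `km_fit` object; `tidy()` gives the step table (`group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`), `glance()` group
#'   sizes, event counts and median survival.
#' @examples
#' d <- tibble::tibble(time = c(1, 2, 3), event = 1)
#' tidy(kaplan_meier(d))  # survival steps 2/3, 1/3, 0
#' @export
kaplan_meier <- function(data, time = "time", event = "event", group = NULL) {
  tt <- data[[time]]; ev <- data[[event]]
  if (is.null(tt) || is.null(ev)) abort("`time`/`event` columns not found.")
  if (any(!is.finite(tt)) || any(tt < 0)) {
    abort("Times must be finite and non-negative.")
  }
  if (!all(ev %in% c(0, 1))) abort("`event` must be 0/1.")
  grp <- if (is.null(group)) rep("all", nrow(data)) else as.character(data[[group]])
  steps <- purrr::map_dfr(split(seq_along(tt), grp), function(idx) {
    km_curve_one(tt[idx], as.integer(ev[idx]))
  }, .id = "group")
  structure(list(steps = as_tibble(steps),
                 group_var = group %||% NULL),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit:", length(unique(x$steps$group)), "group(s),",
      sum(x$steps$n_event), "events\n")
  print(glance(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) x$steps

#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  x$steps %>%
    group_by(group = .data$group) %>%
    summarise(n = max(.data$n_risk),
              n_events = sum(.data$n_event),
              median_survival = {
                i <- which(.data$survival <= 0.5)
                if (length(i)) .data$time[min(i)] else NA_real_
              },
              .groups = "drop")
}

#' Log-rank test
#'
#' The unweighted k-group log-rank chi-square, implemented from first
#' principles: at every pooled distinct event time the observed events per
#' group are compared with their hypergeometric expectations given the
#' at-risk sets, and the accumulated observed-minus-expected vector is
#' referenced against its covariance on `k - 1` degrees of freedom.
#'
#' @inheritParams kaplan_meier
#' @param group Name of the grouping column (required, >= 2 groups).
#' @return A `logrank_test` object with `statistic`, `df`, `p_value` and the
#'   per-group observed/expected table; `glance()` returns them as one row.
#' @export
logrank_test <- function(data, time = "time", event = "event", group = "group") {
  tt <- data[[time]]; ev <- as.integer(data[[event]])
  grp <- factor(data[[group]])
  if (nlevels(grp) < 2L) abort("Need at least 2 groups.")
  if (sum(ev) == 0L) abort("No events observed; the log-rank test is undefined.")
  k <- nlevels(grp)
  event_times <- sort(unique(tt[ev == 1L]))

  obs <- setNames(numeric(k), levels(grp))
  expec <- setNames(numeric(k), levels(grp))
  V <- matrix(0, k, k, dimnames = list(levels(grp), levels(grp)))
  for (t0 in event_times) {
    at_risk <- tt >= t0
    n <- sum(at_risk)
    nj <- tapply(at_risk, grp, sum)
    nj[is.na(nj)] <- 0
    dj <- tapply(ev == 1L & tt == t0, grp, sum)
    dj[is.na(dj)] <- 0
    d <- sum(dj)
    if (n == 0 || d == 0) next
    obs <- obs + dj
    expec <- expec + d * nj / n
    if (n > 1) {
      frac <- nj / n
      vmat <- d * (n - d) / (n - 1) * (diag(frac) - outer(frac, frac))
      V <- V + vmat
    }
  }
  omE <- (obs - expec)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  Vinv <- tryCatch(solve(Vsub), error = function(e) MASS::ginv(Vsub))
  stat <- as.numeric(t(omE) %*% Vinv %*% omE)
  df <- k - 1L
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 table = tibble(group = levels(grp),
                                n = as.integer(table(grp)),
                                observed = as.numeric(obs),
                                expected = as.numeric(expec))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.logrank_test <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test computed by enumeration of the hypergeometric
#' distribution over all tables with the observed margins: the p-value sums
#' the probabilities of every table as or less probable than the observed
#' one (probability-ordering rule). The odds ratio is the sample odds ratio
#' `(a d) / (b c)`, reported as infinite when `b c = 0` and `a d > 0`.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a b / c d`); alternatively pass a 2x2 matrix as `a`.
#' @return A `fisher_enrichment` object with `table`, `odds_ratio`,
#'   `p_value`; `glance()` returns them as one row.
#' @examples
#' glance(fisher_enrichment(5, 5, 5, 5))  # OR 1, p 1
#' @export
fisher_enrichment <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    abort("Degenerate table: every row and column margin must be positive.")
  }
  m <- a + c          # column-1 margin
  nn <- b + d         # column-2 margin
  kk <- a + b         # row-1 margin
  support <- max(0L, kk - nn):min(kk, m)
  probs <- dhyper(support, m, nn, kk)
  p_obs <- dhyper(a, m, nn, kk)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  structure(list(table = matrix(c(a, c, b, d), 2L),
                 odds_ratio = or, p_value = p),
            class = "fisher_enrichment")
}

#' @export
print.fisher_enrichment <- function(x, ...) {
  cat(sprintf("Fisher exact test: OR = %.4g, p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fisher_enrichment <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value)
}
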