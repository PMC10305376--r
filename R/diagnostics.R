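#' Retrieval diagnostics for a single database
#'
#' Each database's yield is judged against the reference set of eligible
#' unique publications identified across *all* databases, using a 2x2
#' contingency table with a pooled-screening-load convention:
#' \describe{
#'   \item{TP}{eligible unique publications present in the database's yield
#'     ("relevant records").}
#'   \item{FP}{the database's pooled yield minus TP -- the irrelevant records
#'     a reviewer would screen, duplicate copies included.}
#'   \item{FN}{eligible unique publications the database missed.}
#'   \item{TN}{pooled corpus size minus the database's yield -- irrelevant
#'     records the database spared the reviewer.}
#' }
#' TP and FN count unique publications while FP and TN count pooled records,
#' so per-database totals differ (total = pooled + eligible - TP). This
#' asymmetry is deliberate: it measures each database against the actual
#' screening workload, and it is preserved rather than "fixed".
#'
#' Sensitivity is TP/(TP+FN) (identical to coverage/recall), specificity is
#' TN/(TN+FP), and accuracy is sensitivity x prevalence + specificity x
#' (1 - prevalence) with prevalence (TP+FN)/total -- algebraically
#' (TP+TN)/total. All interval estimates are exact Clopper-Pearson binomial
#' intervals.
#'
#' @name diagnostics
NULL

#' Construct a 2x2 retrieval contingency table
#'
#' Use this to enter published counts directly; [build_contingency()]
#' derives the table from a labeled corpus.
#'
#' @param tp,fp,fn,tn Non-negative integer counts (see [diagnostics] for
#'   the convention).
#' @param database Optional database label carried for display.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, fn, tn, database = NA_character_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("tp, fp, fn, tn must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 database = database),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  if (!is.na(x$database)) cat(sprintf("Database: %s\n", x$database))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("retrieved", "not retrieved"),
                              c("relevant", "irrelevant")))
  print(m)
  invisible(x)
}

#' Build a database's contingency table from a labeled corpus
#'
#' @param labeled A `labeled_corpus` from [apply_labels()].
#' @param database One database label present in the corpus.
#' @return A `contingency_table` (see [diagnostics] for the convention).
#' @export
build_contingency <- function(labeled, database) {
  stopifnot(inherits(labeled, "labeled_corpus"))
  if (!database %in% labeled$databases)
    stop(sprintf("unknown database label '%s'", database), call. = FALSE)
  covered <- labeled$coverage[, database]
  tp <- sum(covered & labeled$eligible)
  yield <- unname(labeled$yields[database])
  contingency_table(tp = tp, fp = yield - tp,
                    fn = sum(labeled$eligible) - tp,
                    tn = labeled$pooled - yield,
                    database = database)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile bounds: the lower bound is 0 when `k = 0`, else
#' `qbeta(alpha/2, k, n - k + 1)`; the upper bound is 1 when `k = n`, else
#' `qbeta(1 - alpha/2, k + 1, n - k)` with `alpha = 1 - level`. For `k = 0`
#' the upper bound has the closed form `1 - (alpha/2)^(1/n)`. The interval
#' always brackets `k/n` and guarantees at least nominal coverage.
#'
#' @param k Number of successes (`0 <= k <= n`).
#' @param n Number of trials (`> 0`).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)` of proportions.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n <= 0 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integers 0 <= k <= n with n > 0", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || is.na(level) ||
      level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

new_diag_estimate <- function(k, n, level) {
  ci <- clopper_pearson(k, n, level)
  structure(list(point = k / n, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 k = as.integer(k), n = as.integer(n), level = level),
            class = "diag_estimate")
}

#' @export
print.diag_estimate <- function(x, ...) {
  cat(sprintf("%s (%s-%s)  [%d/%d, %.0f%% CI]\n", format_pct(x$point),
              format_pct(x$ci_low), format_pct(x$ci_high), x$k, x$n,
              100 * x$level))
  invisible(x)
}

# half-up rounding to integer percent, the display convention throughout
pct_int <- function(p) floor(100 * p + 0.5)
format_pct <- function(p) sprintf("%d%%", pct_int(p))

#' Retrieval sensitivity (coverage) of a database
#'
#' `TP / (TP + FN)`: the fraction of eligible publications the database
#' indexes.
#'
#' @param ct A `contingency_table`.
#' @param level Confidence level for the exact interval.
#' @return A `diag_estimate` (point, exact CI, k, n).
#' @export
sensitivity <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "contingency_table"))
  n <- ct$tp + ct$fn
  if (n == 0) stop("sensitivity undefined: no eligible publications (tp + fn = 0)",
                   call. = FALSE)
  new_diag_estimate(ct$tp, n, level)
}

#' Retrieval specificity of a database
#'
#' `TN / (TN + FP)`: the fraction of irrelevant screening records the
#' database does not return.
#'
#' @inheritParams sensitivity
#' @return A `diag_estimate`.
#' @export
specificity <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "contingency_table"))
  n <- ct$tn + ct$fp
  if (n == 0) stop("specificity undefined: no irrelevant records (tn + fp = 0)",
                   call. = FALSE)
  new_diag_estimate(ct$tn, n, level)
}

#' Retrieval accuracy of a database
#'
#' Prevalence-weighted average of sensitivity and specificity,
#' `Se x prev + Sp x (1 - prev)` with `prev = (TP+FN)/total`, which reduces
#' algebraically to `(TP+TN)/total`. The interval is the exact binomial
#' interval on `TP+TN` of `total` (a reporting convention; accuracy is a
#' derived quantity and no small-sample interval is canonical).
#'
#' @inheritParams sensitivity
#' @return A `diag_estimate`.
#' @export
accuracy <- function(ct, level = 0.95) {
  stopifnot(inherits(ct, "contingency_table"))
  total <- ct$tp + ct$fp + ct$fn + ct$tn
  if (total == 0) stop("accuracy undefined: empty contingency table", call. = FALSE)
  new_diag_estimate(ct$tp + ct$tn, total, level)
}

#' Per-database diagnostics table
#'
#' One row per database: yield, contingency counts, coverage and the three
#' diagnostic estimates with exact confidence bounds, all as full-precision
#' proportions. `print()` renders integer percents in the style of a
#' published coverage table; use the columns directly for unrounded values.
#'
#' @param labeled A `labeled_corpus`.
#' @param level Confidence level.
#' @return A `data.frame` (class `diagnostics_table`) with columns
#'   `database`, `yield`, `tp`, `fp`, `fn`, `tn`, `se`, `se_low`, `se_high`,
#'   `sp`, `sp_low`, `sp_high`, `ac`, `ac_low`, `ac_high`.
#' @export
diagnostics_table <- function(labeled, level = 0.95) {
  stopifnot(inherits(labeled, "labeled_corpus"))
  rows <- lapply(labeled$databases, function(d) {
    ct <- build_contingency(labeled, d)
    se <- sensitivity(ct, level); sp <- specificity(ct, level)
    ac <- accuracy(ct, level)
    data.frame(database = d, yield = ct$tp + ct$fp,
               tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
               se = se$point, se_low = se$ci_low, se_high = se$ci_high,
               sp = sp$point, sp_low = sp$ci_low, sp_high = sp$ci_high,
               ac = ac$point, ac_low = ac$ci_low, ac_high = ac$ci_high,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), level = level,
            class = c("diagnostics_table", "data.frame"))
}

render_est <- function(p, lo, hi)
  sprintf("%s (%s-%s)", format_pct(p), format_pct(lo), format_pct(hi))

#' @export
print.diagnostics_table <- function(x, ...) {
  out <- data.frame(database = x$database,
                    coverage = sprintf("%d/%d", x$tp, x$tp + x$fn),
                    sensitivity = render_est(x$se, x$se_low, x$se_high),
                    specificity = render_est(x$sp, x$sp_low, x$sp_high),
                    accuracy = render_est(x$ac, x$ac_low, x$ac_high),
                    stringsAsFactors = FALSE)
  print.data.frame(out, row.names = FALSE, right = FALSE)
  invisible(x)
}
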