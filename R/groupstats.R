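#' Split a feature table into low- and high-anxiety groups
#'
#' Ratings of 0-1 form the low-anxiety group, 2-3 the high-anxiety group.
#'
#' @param table a feature table with an `anxiety` column of integer ratings
#'   in `{0, 1, 2, 3}`.
#' @return list with data.frames `low`, `high` and integer vector `counts`.
#' @export
split_groups <- function(table) {
  if (!"anxiety" %in% names(table)) stop("anxiety column missing")
  bad <- which(!table$anxiety %in% 0:3)
  if (length(bad) > 0)
    stop("anxiety rating out of range (0-3) in row ", bad[1],
         ": ", table$anxiety[bad[1]])
  low <- table[table$anxiety <= 1, , drop = FALSE]
  high <- table[table$anxiety >= 2, , drop = FALSE]
  list(low = low, high = high,
       counts = c(low = nrow(low), high = nrow(high)))
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' `d = (m1 - m2) / sp` with `sp = sqrt(((n1-1)s1^2 + (n2-1)s2^2) /
#' (n1+n2-2))`. With group 1 the low-anxiety group and group 2 the
#' high-anxiety group this matches the low-minus-high orientation of the
#' reference study's descriptive table.
#'
#' @param m1,s1,n1 mean, SD, and size of group 1.
#' @param m2,s2,n2 mean, SD, and size of group 2.
#' @return Cohen's d (`NA` with a warning when the pooled SD is zero and
#'   the means differ; 0 when both are degenerate and equal).
#' @export
cohens_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 == m2) return(0)
    warning("zero pooled SD with unequal means: d undefined")
    return(NA_real_)
  }
  (m1 - m2) / sp
}

#' Independent-samples t-test (pooled or Welch)
#'
#' @param x,y numeric samples (each with at least 2 values).
#' @param var_equal pooled-variance Student test when `TRUE` (the default,
#'   matching the reference analysis; `df = n1 + n2 - 2`); Welch otherwise.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
independent_t <- function(x, y, var_equal = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (sd(x) == 0 && sd(y) == 0)
    stop("both samples have zero variance: t undefined")
  res <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Independent-samples t-test from summary statistics (pooled)
#'
#' @inheritParams cohens_d_pooled
#' @return list with `t`, `df`, `p` (two-sided, pooled variance).
#' @export
independent_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  d <- cohens_d_pooled(m1, s1, n1, m2, s2, n2)
  t <- d * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Descriptive-table summary of a feature table
#'
#' Per-variable means and SDs for the total sample and the low/high anxiety
#' groups, with pooled t-tests and low-minus-high Cohen's d, in the shape of
#' the reference study's descriptive table.
#'
#' @param table a feature table with the five acoustic columns and
#'   `anxiety`.
#' @param variables columns to summarise (default: anxiety plus the five
#'   acoustic parameters present).
#' @return a `group_summary` data.frame.
#' @export
group_summary <- function(table, variables = NULL) {
  gr <- split_groups(table)
  if (nrow(gr$low) < 2 || nrow(gr$high) < 2)
    stop("both anxiety groups need at least 2 rows (low = ", nrow(gr$low),
         ", high = ", nrow(gr$high), ")")
  if (is.null(variables))
    variables <- intersect(.vocanet_vars, names(table))
  rows <- lapply(variables, function(v) {
    x <- gr$low[[v]]; y <- gr$high[[v]]
    tt <- independent_t(x, y)
    data.frame(variable = v,
               mean_total = mean(table[[v]]), sd_total = sd(table[[v]]),
               mean_low = mean(x), sd_low = sd(x),
               mean_high = mean(y), sd_high = sd(y),
               t = tt$t, df = tt$df, p = tt$p,
               cohens_d = cohens_d_pooled(mean(x), sd(x), length(x),
                                          mean(y), sd(y), length(y)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", class(out))
  out
}
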