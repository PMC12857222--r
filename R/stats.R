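# Exact paired Wilcoxon signed-rank tests and mean +/- SEM summaries for
# small longitudinal designs (n <= 7 subjects here, so full enumeration of
# the 2^n sign assignments is instant and exact even with midranks).

#' Exact paired Wilcoxon signed-rank test
#'
#' Differences `b - a` are computed per pair; `NA` pairs and zero
#' differences are dropped (classical signed-rank convention), absolute
#' differences are ranked with midranks for ties, and the two-sided
#' p-value is obtained by full enumeration of all `2^n` sign assignments
#' over the observed absolute ranks:
#' `p = P(|W - E(W)| >= |w_plus - E(W)|)` where `E(W)` is the null mean.
#' With no nonzero differences, `p = 1`.
#'
#' @param a,b numeric vectors of paired measurements (same subjects, same
#'   order).
#' @param label optional contrast label carried into the result.
#' @return object of class `comparison_result`: `label`, `n_effective`,
#'   `w_plus`, `p_two_sided`, `direction` (sign of the median difference).
#' @export
signed_rank_exact <- function(a, b, label = NA_character_) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no complete pairs")
  d <- b - a
  dn <- d[d != 0]
  n_eff <- length(dn)
  if (n_eff == 0L) {
    res <- list(label = label, n_effective = 0L, w_plus = 0,
                p_two_sided = 1, direction = 0L)
    class(res) <- "comparison_result"
    return(res)
  }
  if (n_eff > 25L)
    stop("exact enumeration limited to 25 nonzero pairs (got ", n_eff, ")")
  r <- rank(abs(dn))
  w_plus <- sum(r[dn > 0])
  # all 2^n subset sums of the rank vector
  ws <- 0
  for (ri in r) ws <- c(ws, ws + ri)
  e_w <- sum(r) / 2
  eps <- 1e-9
  p <- mean(abs(ws - e_w) >= abs(w_plus - e_w) - eps)
  res <- list(label = label, n_effective = n_eff, w_plus = w_plus,
              p_two_sided = p, direction = sign(stats::median(d)))
  class(res) <- "comparison_result"
  res
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: n = %d, W+ = %g, exact two-sided p = %.6g\n",
              if (is.na(x$label)) "paired signed-rank" else x$label,
              x$n_effective, x$w_plus, x$p_two_sided))
  invisible(x)
}

#' Default planned timepoint contrasts
#'
#' The six biologically anchored day-of-life comparisons: before vs after
#' colostrum (0, 2), birth vs preweaning (0, 42), across weaning (42, 56),
#' into the new barn (56, 90), settling vs oldest sample (90, 285), and
#' birth vs oldest sample (0, 285).
#'
#' @return list of length-2 numeric vectors.
#' @export
default_contrasts <- function() {
  list(c(0, 2), c(0, 42), c(42, 56), c(56, 90), c(90, 285), c(0, 285))
}

#' Run planned paired comparisons over a long-format table
#'
#' Subjects missing either timepoint of a contrast are excluded pairwise,
#' so contrasts involving a timepoint with a missing subject automatically
#' run on the reduced n.
#'
#' @param data data.frame with columns `subject`, `timepoint`, `value`
#'   (rename via the `*_col` arguments).
#' @param contrasts list of timepoint pairs (default [default_contrasts()]).
#' @param subject_col,timepoint_col,value_col column names.
#' @param alpha significance threshold (flag `significant` at `p <= alpha`).
#' @param tendency_max upper bound for the `tendency` flag
#'   (`alpha < p < tendency_max`).
#' @return data.frame: `label`, `timepoint_a`, `timepoint_b`, `n_effective`,
#'   `w_plus`, `p_two_sided`, `direction`, `flag`.
#' @export
planned_comparisons <- function(data, contrasts = default_contrasts(),
                                subject_col = "subject",
                                timepoint_col = "timepoint",
                                value_col = "value",
                                alpha = 0.05, tendency_max = 0.10) {
  need <- c(subject_col, timepoint_col, value_col)
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  tps <- data[[timepoint_col]]
  rows <- lapply(contrasts, function(ct) {
    ta <- ct[1]; tb <- ct[2]
    if (!ta %in% tps) stop("unknown timepoint label: ", ta)
    if (!tb %in% tps) stop("unknown timepoint label: ", tb)
    da <- data[tps == ta, ]
    db <- data[tps == tb, ]
    subjects <- intersect(da[[subject_col]], db[[subject_col]])
    va <- da[[value_col]][match(subjects, da[[subject_col]])]
    vb <- db[[value_col]][match(subjects, db[[subject_col]])]
    label <- sprintf("day %s vs day %s", format(ta), format(tb))
    res <- signed_rank_exact(va, vb, label = label)
    p <- res$p_two_sided
    flag <- if (res$n_effective > 0 && p <= alpha) "significant"
            else if (p > alpha && p < tendency_max) "tendency"
            else ""
    data.frame(label = label, timepoint_a = ta, timepoint_b = tb,
               n_effective = res$n_effective, w_plus = res$w_plus,
               p_two_sided = p, direction = res$direction, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`; undefined (`NA`) when a single value remains.
#'
#' @param values numeric vector.
#' @param na.rm drop `NA`s first?
#' @return list `mean`, `sem`, `n`.
#' @export
mean_sem <- function(values, na.rm = FALSE) {
  if (na.rm) values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("no values")
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}
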