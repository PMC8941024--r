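## Willmott index of agreement between paired measurement series.

#' Willmott index of agreement
#'
#' Standardised 0-1 measure of the degree of similarity between two paired
#' data series: 1.0 indicates a perfect match (two identical series), 0 no
#' agreement at all. With `b` as the reference series and `bbar = mean(b)`,
#' the deviations are `a' = a - bbar`, `b' = b - bbar` and
#'
#'   `d = 1 - sum((a - b)^2) / sum((|a'| + |b'|)^2)`
#'
#' the potential-error denominator of Willmott (1981). When the denominator
#' is 0 - both series constant and equal to `bbar` - the series are identical
#' and `d = 1` by convention.
#'
#' `form = "printed"` selects an alternative denominator,
#' `sum((|a| - |b|)^2)` on the raw values, retained only for auditing
#' transcriptions of the formula: it is undefined (0/0) for identical series
#' and is not bounded to `[0, 1]`. The default form is the one used
#' everywhere in this package.
#'
#' @param a numeric series under evaluation.
#' @param b reference series, same length as `a` (its mean centres both).
#' @param form `"standard"` (default) or `"printed"`.
#' @return The index `d`; in `[0, 1]` for the standard form.
#' @examples
#' willmott_index(c(1, 2, 3), c(1, 2, 3)) # 1: identical series
#' willmott_index(c(1, 2), c(2, 1))       # 0: no agreement
#' @export
willmott_index <- function(a, b, form = c("standard", "printed")) {
  form <- match.arg(form)
  if (length(a) != length(b)) stop("`a` and `b` must have the same length")
  if (length(a) < 2L) stop("need at least 2 paired observations")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed after pairing")
  num <- sum((a - b)^2)
  if (form == "printed") {
    den <- sum((abs(a) - abs(b))^2)
    return(1 - num / den)
  }
  bbar <- mean(b)
  den <- sum((abs(a - bbar) + abs(b - bbar))^2)
  if (den == 0) return(1) # both series constant at bbar: identical
  1 - num / den
}

#' Monthly Willmott agreement table
#'
#' Computes one Willmott index per month for each labelled pair of series,
#' the machine-readable analogue of a monthly agreement figure. Months with
#' fewer than 2 paired points are omitted with a warning.
#'
#' @param x data frame with a month column and the paired series columns.
#' @param pairs named list; each element is `c(a_column, b_column)` with the
#'   second column taken as the reference series.
#' @param month name of the month column.
#' @return Data frame with columns `month`, `pair`, `d`, `n`.
#' @export
monthly_willmott <- function(x, pairs, month = "month") {
  if (!month %in% names(x)) stop("no `", month, "` column in `x`")
  out <- list()
  for (lab in names(pairs)) {
    cols <- pairs[[lab]]
    if (length(cols) != 2L || !all(cols %in% names(x))) {
      stop("pair `", lab, "` must name two columns of `x`")
    }
    for (m in unique(x[[month]])) {
      g <- x[x[[month]] == m, ]
      ok <- stats::complete.cases(g[, cols])
      if (sum(ok) < 2L) {
        warning("month ", m, ", pair ", lab, ": fewer than 2 paired points; omitted")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        month = m, pair = lab,
        d = willmott_index(g[ok, cols[1L]], g[ok, cols[2L]]),
        n = sum(ok), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) return(data.frame(month = integer(), pair = character(),
                                      d = numeric(), n = integer()))
  do.call(rbind, out)
}
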