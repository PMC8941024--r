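## Comparison battery: equal-proportions mortality test, normality routing,
## two-way factorial ANOVA with Tukey letters, Scheirer-Ray-Hare rank test,
## and Dunn's post-hoc test with FDR correction.

#' Test of equal proportions for a two-environment mortality table
#'
#' Pearson chi-square test (1 df) that the mortality proportion is the same
#' in the two environments, with optional Yates continuity correction.
#' Delegates to [stats::prop.test()].
#'
#' @param deaths integer vector of length 2, deaths per environment.
#' @param n integer vector of length 2, founding queens per environment.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return An object of class `"htest"`.
#' @examples
#' equal_proportions_test(c(91, 58), c(100, 100))
#' @export
equal_proportions_test <- function(deaths, n, correct = FALSE) {
  if (length(deaths) != 2L || length(n) != 2L) {
    stop("`deaths` and `n` must each have length 2")
  }
  if (any(n <= 0)) stop("both environments need at least one founding queen")
  if (any(deaths < 0) || any(deaths > n)) stop("`deaths` must lie in [0, n]")
  if (sum(deaths) == 0 || sum(n - deaths) == 0) {
    stop("degenerate table: a zero marginal makes the chi-square undefined")
  }
  stats::prop.test(deaths, n, correct = correct)
}

#' Route a sample to the parametric or nonparametric branch
#'
#' Shapiro-Wilk normality gate: if the Shapiro-Wilk p-value is at least
#' `alpha` the sample is routed to the parametric branch (ANOVA + Tukey),
#' otherwise to the nonparametric branch (Scheirer-Ray-Hare + Dunn). A
#' constant sample cannot come from a continuous normal population and is
#' routed nonparametric (the W statistic is undefined there).
#'
#' @param x numeric sample, length >= 3.
#' @param alpha significance level of the gate (default 0.05).
#' @return List with `route` (`"parametric"`/`"nonparametric"`), `W`, and
#'   `p_value`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  if (length(x) < 3L) stop("normality gate needs at least 3 observations")
  if (stats::sd(x) == 0) {
    return(list(route = "nonparametric", W = NA_real_, p_value = NA_real_))
  }
  sw <- stats::shapiro.test(x)
  list(
    route = if (sw$p.value >= alpha) "parametric" else "nonparametric",
    W = unname(sw$statistic),
    p_value = sw$p.value
  )
}

## ---- compact letter display ---------------------------------------------

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter do not differ at the
#' chosen level. `p` is a symmetric matrix of (adjusted) pairwise p-values
#' with group names on the dimnames. Groups are lettered in the order given
#' by `order` (typically decreasing group mean or median); ties in that
#' ordering are broken by group label.
#'
#' @param p symmetric matrix of pairwise p-values.
#' @param alpha significance level.
#' @param order optional character vector giving the display order of groups.
#' @return Named character vector of letter codes, one per group.
#' @export
letter_display <- function(p, alpha = 0.05, order = NULL) {
  groups <- rownames(p)
  if (is.null(groups)) stop("`p` needs dimnames naming the groups")
  if (is.null(order)) order <- sort(groups)
  stopifnot(setequal(order, groups))
  # start from one column holding every group; for each significant pair,
  # split every column containing both; then absorb columns contained in
  # another (Piepho-style insert-and-absorb)
  cols <- list(order)
  sig <- which(p < alpha & upper.tri(p), arr.ind = TRUE)
  for (k in seq_len(nrow(sig))) {
    gi <- groups[sig[k, 1L]]
    gj <- groups[sig[k, 2L]]
    newcols <- list()
    for (col in cols) {
      if (gi %in% col && gj %in% col) {
        newcols <- c(newcols, list(setdiff(col, gi), setdiff(col, gj)))
      } else {
        newcols <- c(newcols, list(col))
      }
    }
    keep <- rep(TRUE, length(newcols))
    for (i in seq_along(newcols)) {
      for (j in seq_along(newcols)) {
        if (i == j || !keep[i] || !keep[j]) next
        sub <- all(newcols[[i]] %in% newcols[[j]])
        proper <- sub && length(newcols[[i]]) < length(newcols[[j]])
        dup <- sub && !proper && i > j
        if (proper || dup) keep[i] <- FALSE
      }
    }
    cols <- newcols[keep]
  }
  # letter order follows the requested group ordering
  first_pos <- vapply(cols, function(col) min(match(col, order)), numeric(1))
  cols <- cols[base::order(first_pos)]
  out <- stats::setNames(rep("", length(groups)), order)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out[groups]
}

## ---- two-way ANOVA + Tukey -----------------------------------------------

#' Two-way factorial ANOVA with Tukey multiple comparisons and letters
#'
#' Fits `response ~ factor_a * factor_b` by [stats::aov()], reports the F
#' tests for both main effects and their interaction, runs Tukey's HSD on
#' each main factor, and summarises each factor's levels with a compact
#' letter display (levels sharing a letter do not differ at `alpha`).
#'
#' @param response numeric response.
#' @param factor_a,factor_b factors (coerced); every crossed cell must be
#'   non-empty.
#' @param alpha significance level for the letters (default 0.05).
#' @return Object of class `"nestclim_anova"`: a list with `anova` (tidy
#'   table of effects), `tukey` (per-factor pairwise tables) and `letters`
#'   (per-factor letter codes).
#' @export
two_way_anova_tukey <- function(response, factor_a, factor_b, alpha = 0.05) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (any(table(a, b) == 0)) stop("every factor cell needs at least one observation")
  dat <- data.frame(y = response, A = a, B = b)
  fit <- stats::aov(y ~ A * B, data = dat)
  tab <- as.data.frame(summary(fit)[[1L]])
  eff <- trimws(rownames(tab))
  aov_tab <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residuals")[match(eff, c("A", "B", "A:B", "Residuals"))],
    df = tab$Df, sum_sq = tab$`Sum Sq`, statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`, stringsAsFactors = FALSE
  )
  tk <- stats::TukeyHSD(fit, which = c("A", "B"))
  letters_of <- function(which, f) {
    m <- tk[[which]]
    lv <- levels(f)
    p <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
    pairs <- strsplit(rownames(m), "-", fixed = TRUE)
    for (k in seq_along(pairs)) {
      p[pairs[[k]][1L], pairs[[k]][2L]] <- m[k, "p adj"]
      p[pairs[[k]][2L], pairs[[k]][1L]] <- m[k, "p adj"]
    }
    means <- tapply(dat$y, f, mean)
    letter_display(p, alpha = alpha, order = names(sort(-means)))
  }
  structure(list(
    anova = aov_tab,
    tukey = lapply(tk, as.data.frame),
    letters = list(factor_a = letters_of("A", dat$A), factor_b = letters_of("B", dat$B)),
    alpha = alpha
  ), class = "nestclim_anova")
}

#' @export
print.nestclim_anova <- function(x, ...) {
  cat("Two-way factorial ANOVA with Tukey HSD (alpha =", x$alpha, ")\n\n")
  print(x$anova, row.names = FALSE)
  cat("\nLetters (factor_a):", paste(names(x$letters$factor_a),
      x$letters$factor_a, sep = ":", collapse = "  "), "\n")
  cat("Letters (factor_b):", paste(names(x$letters$factor_b),
      x$letters$factor_b, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

## ---- Scheirer-Ray-Hare ----------------------------------------------------

# Type-II sums of squares on ranks via nested least-squares fits; reduces to
# the classical decomposition for balanced designs.
.rank_ss <- function(r, A, B) {
  dat <- data.frame(r = r, A = A, B = B)
  rss <- function(f) sum(stats::resid(stats::lm(f, data = dat))^2)
  rss_full <- rss(r ~ A * B)
  rss_ab <- rss(r ~ A + B)
  list(
    A = rss(r ~ B) - rss_ab,
    B = rss(r ~ A) - rss_ab,
    AB = rss_ab - rss_full,
    residual = rss_full,
    total = sum((r - mean(r))^2)
  )
}

#' Scheirer-Ray-Hare rank test for a two-way factorial design
#'
#' Nonparametric extension of the Kruskal-Wallis test to a two-factor
#' completely randomized design. The pooled response is replaced by mid-ranks
#' (which absorb the tie adjustment), a factorial sum-of-squares
#' decomposition is computed on the ranks, and each effect's statistic is
#' `H = SS_effect / MS_total` with `MS_total = SS_total / (N - 1)`, referred
#' to a chi-square distribution with the effect's degrees of freedom. When
#' one factor is held at a single level the other factor's `H` equals the
#' (tie-corrected) Kruskal-Wallis statistic.
#'
#' Balanced designs use the closed-form decomposition; unbalanced designs
#' fall back to type-II sums of squares on the ranks.
#'
#' @param response numeric response.
#' @param factor_a,factor_b factors (coerced).
#' @return Object of class `"srh"`: a data frame of effects with columns
#'   `effect`, `df`, `ss`, `H`, `p_value`.
#' @export
scheirer_ray_hare <- function(response, factor_a, factor_b) {
  A <- factor(factor_a)
  B <- factor(factor_b)
  y <- as.numeric(response)
  if (length(y) != length(A) || length(y) != length(B)) {
    stop("`response` and factors must have equal length")
  }
  N <- length(y)
  if (N < 2L) stop("need at least 2 observations")
  r <- rank(y) # mid-ranks for ties
  ss_total <- sum((r - mean(r))^2)
  if (ss_total == 0) stop("all responses are tied; rank variance is zero")
  ms_total <- ss_total / (N - 1)

  counts <- table(A, B)
  balanced <- length(unique(as.vector(counts))) == 1L && all(counts > 0)
  dfA <- nlevels(A) - 1L
  dfB <- nlevels(B) - 1L
  oneway_ss <- function(f) {
    m <- tapply(r, f, mean)
    sum(tabulate(f, nbins = nlevels(f)) * (m - mean(r))^2)
  }
  if (dfA == 0L || dfB == 0L) {
    # one factor held at a single level: Kruskal-Wallis on the other
    ssA <- if (dfA > 0L) oneway_ss(A) else 0
    ssB <- if (dfB > 0L) oneway_ss(B) else 0
    ss <- list(A = ssA, B = ssB, AB = 0,
               residual = ss_total - ssA - ssB, total = ss_total)
  } else if (balanced) {
    rbar <- mean(r)
    mA <- tapply(r, A, mean); nA <- tabulate(A)
    mB <- tapply(r, B, mean); nB <- tabulate(B)
    cellm <- tapply(r, list(A, B), mean)
    ncell <- counts[1L, 1L]
    ssA <- sum(nA * (mA - rbar)^2)
    ssB <- sum(nB * (mB - rbar)^2)
    ss_cells <- sum(ncell * (cellm - rbar)^2)
    ssAB <- ss_cells - ssA - ssB
    ss <- list(A = ssA, B = ssB, AB = ssAB,
               residual = ss_total - ss_cells, total = ss_total)
  } else {
    if (any(counts == 0)) {
      # empty cells: drop the interaction, additive type-II decomposition
      ss <- .rank_ss(r, A, B)
      ss$AB <- NA_real_
    } else {
      ss <- .rank_ss(r, A, B)
    }
  }
  dfAB <- dfA * dfB
  eff <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "residuals", "total"),
    df = c(dfA, dfB, dfAB, N - 1L - dfA - dfB - dfAB, N - 1L),
    ss = c(ss$A, ss$B, ss$AB, ss$residual, ss$total),
    stringsAsFactors = FALSE
  )
  eff$H <- eff$ss / ms_total
  eff$H[eff$effect %in% c("residuals", "total")] <- NA_real_
  eff$p_value <- ifelse(is.na(eff$H) | eff$df == 0, NA_real_,
                        stats::pchisq(eff$H, eff$df, lower.tail = FALSE))
  structure(eff, class = c("srh", "data.frame"), ms_total = ms_total)
}

#' @export
print.srh <- function(x, ...) {
  cat("Scheirer-Ray-Hare rank test (two-way factorial)\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

## ---- Dunn's test -----------------------------------------------------------

#' Dunn's test of multiple comparisons with FDR correction
#'
#' Rank-based pairwise post-hoc comparisons following a Kruskal-Wallis-type
#' omnibus test. All groups are ranked together (mid-ranks for ties) and each
#' pair is compared with
#'
#'   `z_ij = (Rbar_i - Rbar_j) / sqrt(sigma2 * (1/n_i + 1/n_j))`
#'
#' where `sigma2 = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))` carries the tie
#' adjustment. Two-sided p-values are adjusted by the Benjamini-Hochberg
#' false-discovery-rate procedure (default) and summarised with a compact
#' letter display: groups sharing a letter do not differ at `alpha`.
#'
#' @param x numeric response.
#' @param g group labels (coerced to factor); >= 2 non-empty groups.
#' @param p_adjust `"fdr"` (Benjamini-Hochberg, default) or `"none"`.
#' @param alpha significance level for the letter display.
#' @return Object of class `"dunn"`: list with `comparisons` (pairwise table
#'   with `z`, `p_value`, `p_adjusted`) and `letters`.
#' @export
dunn_test <- function(x, g, p_adjust = c("fdr", "none"), alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  g <- as.factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g, nbins = nlevels(g)) == 0L)) {
    stop("every group needs at least one observation")
  }
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  lv <- levels(g)
  pairs <- utils::combn(seq_along(lv), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(sigma2 * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- if (p_adjust == "fdr") stats::p.adjust(p, method = "BH") else p
  comp <- data.frame(
    group_i = lv[pairs[1L, ]], group_j = lv[pairs[2L, ]],
    z = z, p_value = p, p_adjusted = p_adj, stringsAsFactors = FALSE
  )
  pm <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  for (k in seq_len(ncol(pairs))) {
    pm[pairs[1L, k], pairs[2L, k]] <- p_adj[k]
    pm[pairs[2L, k], pairs[1L, k]] <- p_adj[k]
  }
  med <- tapply(x, g, stats::median)
  structure(list(
    comparisons = comp,
    letters = letter_display(pm, alpha = alpha, order = names(sort(-med))),
    sigma2 = sigma2, alpha = alpha, adjustment = p_adjust
  ), class = "dunn")
}

#' @export
print.dunn <- function(x, ...) {
  cat("Dunn's multiple comparisons (adjustment:", x$adjustment, ")\n\n")
  print(x$comparisons, row.names = FALSE, digits = 4)
  cat("\nLetters:", paste(names(x$letters), x$letters, sep = ":",
      collapse = "  "), "\n")
  invisible(x)
}
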