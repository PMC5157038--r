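#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way analysis of variance (equal-variance F
#' test) across `k >= 2` groups, via `stats::oneway.test(var.equal = TRUE)`.
#' Degenerate inputs: if all values are identical across all groups the
#' result is `F = 0, p = 1` by convention; zero within-group variance with
#' unequal means is an error.
#'
#' @param groups list of numeric vectors, each of length >= 2
#' @return a `group_stats_result`: list with `f`, `df` (between, within),
#'   `p`, and a `groups` tibble (mean, sd, n per group)
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  k <- length(groups)
  N <- sum(lengths(groups))
  summ <- tibble::tibble(
    group = if (is.null(names(groups))) as.character(seq_len(k)) else
      names(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0),
    n = lengths(groups))
  if (all(summ$sd == 0)) {
    if (length(unique(summ$mean)) == 1L)
      return(structure(list(f = 0, df = c(k - 1, N - k), p = 1,
                            groups = summ), class = "group_stats_result"))
    stop("zero within-group variance with unequal means")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), lengths(groups)))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(
    list(f = unname(ft$statistic),
         df = unname(c(ft$parameter[["num df"]], ft$parameter[["denom df"]])),
         p = unname(ft$p.value), groups = summ),
    class = "group_stats_result"
  )
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.2f, p = %.3f\n",
              x$df[1], x$df[2], x$f, x$p))
  if (!is.null(x$posthoc)) {
    cat(sprintf("Post-hoc two-tailed t-tests (Bonferroni alpha = %.4f):\n",
                x$alpha_corrected))
    print(as.data.frame(x$posthoc), digits = 3)
  }
  invisible(x)
}

#' One-way ANOVA from published summary statistics
#'
#' Recomputes the one-way F statistic from per-group means, standard
#' deviations and sizes alone:
#' `MS_between = sum n_i (m_i - m_bar)^2 / (k - 1)` with `m_bar` the
#' size-weighted grand mean, and
#' `MS_within = sum (n_i - 1) s_i^2 / (N - k)`. This is algebraically
#' identical to [one_way_anova()] on any raw data having those summaries,
#' which makes printed group tables directly checkable.
#'
#' @param means,sds,ns equal-length numeric vectors of group means, sample
#'   standard deviations, and sizes (each `n >= 2`)
#' @return a `group_stats_result` (see [one_way_anova()])
#' @export
anova_from_summary <- function(means, sds, ns) {
  if (length(means) != length(sds) || length(means) != length(ns))
    stop("means, sds, ns must have equal length")
  stopifnot(all(ns >= 2))
  k <- length(means)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ms_between <- sum(ns * (means - grand)^2) / (k - 1)
  ms_within <- sum((ns - 1) * sds^2) / (N - k)
  summ <- tibble::tibble(group = as.character(seq_len(k)),
                         mean = means, sd = sds, n = as.integer(ns))
  if (ms_within == 0) {
    if (ms_between == 0)
      return(structure(list(f = 0, df = c(k - 1, N - k), p = 1,
                            groups = summ), class = "group_stats_result"))
    stop("zero within-group variance with unequal means")
  }
  f <- ms_between / ms_within
  structure(
    list(f = f, df = c(k - 1, N - k),
         p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
         groups = summ),
    class = "group_stats_result"
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level
#' @param m number of comparisons (>= 1)
#' @return `alpha / m` (0.05 over 3 pairwise tests gives 0.0167, commonly
#'   reported rounded as 0.017)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Post-hoc pairwise t-tests with Bonferroni correction
#'
#' Two-tailed Student t-tests on all `k (k - 1) / 2` group pairs, flagged
#' significant at the Bonferroni-corrected level `alpha / n_pairs`.
#' Independent two-sample tests with pooled variance by default; `paired =
#' TRUE` switches to paired tests (requires equal group sizes). Post-hoc
#' testing is conventionally gated on a significant omnibus ANOVA: pass the
#' ANOVA result as `gate` to enforce this (an error when the gate fails).
#'
#' @param groups list of numeric vectors
#' @param alpha family-wise significance level
#' @param paired use paired t-tests
#' @param gate optional `group_stats_result`; when given, requires
#'   `gate$p < alpha`
#' @return tibble with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p`, `significant` (after correction), plus attribute-free columns
#'   `alpha_corrected`
#' @export
posthoc_ttests <- function(groups, alpha = 0.05, paired = FALSE,
                           gate = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (!is.null(gate) && gate$p >= alpha)
    stop(sprintf("omnibus ANOVA not significant (p = %.3f >= %.2f); %s",
                 gate$p, alpha, "post-hoc tests not warranted"))
  k <- length(groups)
  nm <- if (is.null(names(groups))) as.character(seq_len(k)) else
    names(groups)
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  thr <- bonferroni_threshold(alpha, m)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- groups[[i1]]; b <- groups[[i2]]
    if (paired && length(a) != length(b))
      stop("paired = TRUE requires equal group sizes")
    if (stats::sd(c(a, b)) == 0) {
      tt <- list(statistic = 0,
                 parameter = if (paired) length(a) - 1 else
                   length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE, paired = paired)
    }
    tibble::tibble(group1 = nm[i1], group2 = nm[i2],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, alpha_corrected = thr,
                   significant = tt$p.value < thr)
  })
  do.call(rbind, rows)
}

#' Omnibus ANOVA with gated Bonferroni post-hoc tests
#'
#' Convenience wrapper running [one_way_anova()] and, when the omnibus test
#' is significant at `alpha`, [posthoc_ttests()] on the same groups.
#'
#' @param groups named list of numeric vectors
#' @param alpha family-wise significance level
#' @param paired passed to [posthoc_ttests()]
#' @return a `group_stats_result` with `posthoc` (tibble or `NULL`) and
#'   `alpha_corrected` fields added
#' @export
rate_effect_test <- function(groups, alpha = 0.05, paired = FALSE) {
  res <- one_way_anova(groups)
  res$alpha <- alpha
  res$alpha_corrected <- bonferroni_threshold(
    alpha, length(groups) * (length(groups) - 1) / 2)
  res$posthoc <- if (res$p < alpha)
    posthoc_ttests(groups, alpha = alpha, paired = paired, gate = res)
  res
}
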