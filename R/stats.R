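#' Welch two-sample t-test
#'
#' Two-tailed unpaired t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), as used for all two-group
#' density comparisons. Wraps [stats::t.test()] with `var.equal = FALSE`.
#' Degenerate inputs where both groups have zero variance are handled by
#' convention: equal means give `t = 0, p = 1`; unequal means give
#' `t = +/-Inf, p = 0`.
#'
#' @param a,b numeric vectors (each `n >= 2`, finite).
#' @return `list(t, df, p)`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Step-down Sidak-Holm p-value adjustment
#'
#' Orders the raw p-values ascending and adjusts the i-th (of m) as
#' `1 - (1 - p_i)^(m - i + 1)`, then enforces monotone non-decreasing
#' adjusted values (step-down). Returned in the input order.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
sidak_holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way ANOVA with Sidak-Holm-corrected pairwise comparisons
#'
#' Omnibus one-way ANOVA (equal-variance F-test via [stats::aov()]) over
#' three or more groups, followed by all pairwise Welch t-tests whose raw
#' p-values are corrected by the step-down Sidak-Holm procedure
#' ([sidak_holm_adjust()]); plain Holm-Bonferroni is available via
#' `method = "holm"`.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each `n >= 2`).
#' @param method `"sidak_holm"` (default) or `"holm"`.
#' @return `list(F, df1, df2, p, pairwise)` where `pairwise` is a
#'   `data.table` with `group1`, `group2`, `t`, `df`, `p_raw`, `p_adj`.
#' @export
anova_sidak_holm <- function(groups, method = c("sidak_holm", "holm")) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 3L)
    stop("need at least 3 groups; for two groups use welch_t()")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2L)) stop("each group needs n >= 2")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L)))
  )
  at <- anova(aov(value ~ group, data = df))
  pairs <- utils::combn(names(groups), 2L)
  pw <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    wt <- welch_t(groups[[g1]], groups[[g2]])
    data.table::data.table(group1 = g1, group2 = g2,
                           t = wt$t, df = wt$df, p_raw = wt$p)
  }))
  pw[, p_adj := if (method == "sidak_holm") sidak_holm_adjust(p_raw)
     else stats::p.adjust(p_raw, method = "holm")]
  list(F = at$`F value`[1L], df1 = at$Df[1L], df2 = at$Df[2L],
       p = at$`Pr(>F)`[1L], pairwise = pw[])
}

#' Signed percent change
#'
#' `100 * (after - before) / before`; `before` must be positive.
#'
#' @param before,after numeric values, `before > 0`.
#' @return Signed percentage.
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(before <= 0))
    stop("percent change undefined for before <= 0")
  100 * (after - before) / before
}

#' Clinical response labeling from lesion-severity scores
#'
#' A patient is a `responder` iff the composite lesion score decreased by at
#' least 50% from baseline: `(before - after) / before >= 0.5` (the exact
#' 50% boundary is a response). Scores must be non-negative and the baseline
#' positive.
#'
#' @param cails_before,cails_after numeric score(s).
#' @return Character vector, `"responder"` or `"non_responder"`.
#' @export
classify_responder <- function(cails_before, cails_after) {
  if (any(cails_before < 0) || any(cails_after < 0))
    stop("scores must be >= 0")
  if (any(cails_before <= 0)) stop("baseline score must be > 0")
  ifelse((cails_before - cails_after) / cails_before >= 0.5,
         "responder", "non_responder")
}

#' Median with quartiles (violin-plot summary)
#'
#' Median and 25th/75th percentiles using linear interpolation between order
#' statistics ([stats::quantile()] type 7).
#'
#' @param x numeric vector.
#' @return Named numeric `c(q25, median, q75)`.
#' @export
violin_summary <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], median = q[2], q75 = q[3])
}
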