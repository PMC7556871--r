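#' Unpaired two-sided t-test with F-test variance screening
#'
#' Implements the comparison policy used throughout this kind of study:
#' equality of variances is first checked with a two-sided F-test; if it
#' is not rejected (p >= `f_alpha`) a pooled-variance Student t-test is
#' used, otherwise the Welch approximation. The variance decision is
#' recorded in the result. Both tests are two-sided.
#'
#' @param a,b numeric samples, each of length >= 2, finite.
#' @param f_alpha significance level of the variance screen.
#' @param pool_always skip the screen and always pool (for strict
#'   Student-t reporting).
#' @return object of class `"comparison_result"`: a list with `test`
#'   (`"t_unpaired"` or `"welch_t"`), `statistic`, `df`, `p_value`,
#'   `f_test` (statistic, df, p of the variance screen),
#'   `group_summaries` (n, mean, SEM per group).
#' @export
ttest_unpaired <- function(a, b, f_alpha = 0.05, pool_always = FALSE) {
  check_sample <- function(x, name) {
    if (length(x) < 2L || !all(is.finite(x))) {
      stop(sprintf("`%s` must hold >= 2 finite values", name),
           call. = FALSE)
    }
  }
  check_sample(a, "a"); check_sample(b, "b")
  degenerate <- var(a) == 0 && var(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    res <- list(test = "t_unpaired", statistic = 0,
                df = length(a) + length(b) - 2, p_value = 1,
                f_test = NULL, degenerate = TRUE,
                group_summaries = group_summaries(list(a = a, b = b)))
    class(res) <- "comparison_result"
    return(res)
  }
  ft <- if (degenerate) NULL else var.test(a, b)
  pooled <- pool_always || is.null(ft) || ft$p.value >= f_alpha
  tt <- t.test(a, b, var.equal = pooled)
  res <- list(
    test = if (pooled) "t_unpaired" else "welch_t",
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    f_test = if (!is.null(ft)) {
      list(statistic = unname(ft$statistic), df = unname(ft$parameter),
           p_value = ft$p.value)
    },
    degenerate = FALSE,
    group_summaries = group_summaries(list(a = a, b = b))
  )
  class(res) <- "comparison_result"
  res
}

#' One-way ANOVA with Fisher LSD post hoc comparisons
#'
#' Ordinary one-way ANOVA followed by Fisher's least-significant-difference
#' procedure: every pair of groups is compared with
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))` on `N - k`
#' degrees of freedom using the pooled ANOVA error term. LSD p-values are
#' deliberately unadjusted for multiplicity — that is the definition of
#' the procedure. With two groups it reduces exactly to the pooled t-test.
#'
#' @param groups named list of >= 2 numeric samples, each length >= 2.
#' @return object of class `"comparison_result"`: `test = "anova_lsd"`,
#'   `statistic` (F), `df` (c(between, within)), `p_value`, `mse`,
#'   `group_summaries`, and `pairwise` (data.frame `group1`, `group2`,
#'   `mean_diff`, `t`, `p_value`).
#' @export
anova_lsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  fit <- aov(y ~ g)
  an <- anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  df_w <- an["Residuals", "Df"]
  fstat <- an["g", "F value"]
  pval <- an["g", "Pr(>F)"]
  if (is.na(fstat)) {  # all groups identical: zero between and within SS
    fstat <- 0; pval <- 1
  }
  nm <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1L, c2]; j <- pairs[2L, c2]
    ni <- length(groups[[i]]); nj <- length(groups[[j]])
    diff_ij <- mean(groups[[i]]) - mean(groups[[j]])
    se <- sqrt(mse * (1 / ni + 1 / nj))
    tstat <- if (se == 0) {
      if (diff_ij == 0) 0 else Inf * sign(diff_ij)
    } else {
      diff_ij / se
    }
    p <- if (is.finite(tstat)) 2 * pt(-abs(tstat), df_w) else 0
    data.frame(group1 = nm[i], group2 = nm[j], mean_diff = diff_ij,
               t = tstat, p_value = p, stringsAsFactors = FALSE)
  }))
  res <- list(test = "anova_lsd", statistic = fstat,
              df = c(between = an["g", "Df"], within = df_w),
              p_value = pval, mse = mse,
              group_summaries = group_summaries(groups), pairwise = pw)
  class(res) <- "comparison_result"
  res
}

group_summaries <- function(groups) {
  data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(x) sd(x) / sqrt(length(x)), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.4g, p = %.4g %s\n",
              x$test, x$statistic, x$p_value,
              significance_stars(x$p_value)))
  print(x$group_summaries)
  if (!is.null(x$pairwise)) {
    cat("pairwise (Fisher LSD, unadjusted):\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Significance stars at the conventional thresholds
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings (empty when p >= 0.05).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***"
    else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Mean +/- SEM report table by group
#'
#' @param data data.frame with the metric in `value_col` and group labels
#'   in `group_col`.
#' @param value_col,group_col column names.
#' @param p optional named numeric vector of p-values per group (e.g. from
#'   pairwise comparisons against a control) used to attach significance
#'   stars.
#' @return data.frame: `group`, `n`, `mean`, `sem` (and `stars` when `p`
#'   is given). Empty groups are omitted with a warning.
#' @export
summarize_groups <- function(data, value_col = "value",
                             group_col = "group", p = NULL) {
  stopifnot(all(c(value_col, group_col) %in% names(data)))
  g <- data[[group_col]]
  all_levels <- if (is.factor(g)) levels(g) else unique(as.character(g))
  empty <- setdiff(all_levels, unique(as.character(g)))
  if (length(empty)) {
    warning(sprintf("empty group(s) omitted: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  parts <- split(data[[value_col]], as.character(g))
  out <- group_summaries(parts)
  if (!is.null(p)) {
    out$stars <- significance_stars(unname(p[out$group]))
  }
  out
}
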