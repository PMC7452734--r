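#' Group summary: mean, SEM, n
#'
#' @param values Numeric vector of per-animal metric values (n >= 2).
#' @return List with `mean`, `sem` (sample SD / sqrt(n)), `n`.
#' @export
#' @examples
#' group_summary(c(1, 2, 3))  # sem = 1/sqrt(3)
group_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values per group")
  if (!all(is.finite(values))) stop("group values must be finite")
  n <- length(values)
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Two-tailed unpaired Student's t test
#'
#' Pooled-variance Student's t with `df = n_a + n_b - 2` and a two-tailed
#' p value. Degenerate inputs with zero pooled variance follow the
#' documented convention: p = 1 when the means are equal, p = 0
#' otherwise.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param conf_level Confidence level of the CI of the difference.
#' @return List with `t`, `df`, `p`, `estimate` (mean(a) - mean(b)),
#'   `ci_low`, `ci_high`, `conf_level`.
#' @export
t_test_unpaired <- function(a, b, conf_level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  diff <- mean(a) - mean(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0) {
    p <- if (diff == 0) 1 else 0
    tstat <- if (diff == 0) 0 else sign(diff) * Inf
    ci <- c(diff, diff)
  } else {
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tstat <- diff / se
    p <- 2 * stats::pt(-abs(tstat), df)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- diff + c(-1, 1) * tcrit * se
  }
  list(t = tstat, df = df, p = p, estimate = diff,
       ci_low = ci[1L], ci_high = ci[2L], conf_level = conf_level)
}

# one-way fixed-effects ANOVA decomposition for a list of numeric vectors
oneway_anova <- function(groups) {
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- sum(ns) - length(groups)
  msw <- ssw / dfw
  f <- if (msw == 0) {
    if (ssb == 0) 0 else Inf
  } else {
    (ssb / dfb) / msw
  }
  p <- if (is.finite(f)) stats::pf(f, dfb, dfw, lower.tail = FALSE) else 0
  list(f = f, p = p, df1 = dfb, df2 = dfw, msw = msw,
       ns = ns, means = means)
}

#' One-way ANOVA with Tukey's multiple comparison test
#'
#' Fixed-effects one-way ANOVA followed by Tukey HSD pairwise comparisons
#' using the studentized-range distribution with the Tukey-Kramer
#' unequal-n correction. Each pairwise row reports the simultaneous
#' `1 - alpha` CI of the mean difference and an adjusted p value;
#' `significant` is `p < alpha`, which for Tukey rows coincides with 0
#' lying outside the CI. Pairs are ordered following the order the groups
#' are supplied (first vs second, first vs third, second vs third, ...).
#'
#' @param groups Named list of numeric vectors, >= 3 groups with n >= 2
#'   each. With 2 groups the function stops and directs the caller to
#'   [t_test_unpaired()].
#' @param alpha Family-wise significance level.
#' @return List of class `anova_tukey` with `f`, `p`, `df1`, `df2`, and
#'   `comparisons`: a data.frame with columns `description`, `method`,
#'   `estimate`, `ci_low`, `ci_high`, `significant`, `p_value`.
#' @export
#' @examples
#' g <- list(control = c(5, 6, 7), low = c(8, 9, 10), high = c(2, 3, 4))
#' anova_tukey(g)$comparisons
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L) {
    stop("anova_tukey needs >= 3 groups; use t_test_unpaired() for 2 groups")
  }
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, as.numeric)
  av <- oneway_anova(groups)
  k <- length(groups)
  qcrit <- stats::qtukey(1 - alpha, k, av$df2)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    diff <- av$means[i] - av$means[j]
    se_tk <- sqrt(av$msw / 2 * (1 / av$ns[i] + 1 / av$ns[j]))
    if (se_tk == 0) {
      pv <- if (diff == 0) 1 else 0
      ci <- c(diff, diff)
    } else {
      qstat <- abs(diff) / se_tk
      pv <- stats::ptukey(qstat, k, av$df2, lower.tail = FALSE)
      ci <- diff + c(-1, 1) * qcrit * se_tk
    }
    data.frame(description = paste(names(groups)[i], "vs", names(groups)[j]),
               method = "anova_tukey",
               estimate = unname(diff),
               ci_low = ci[1L], ci_high = ci[2L],
               significant = pv < alpha,
               p_value = pv)
  })
  structure(list(f = av$f, p = av$p, df1 = av$df1, df2 = av$df2,
                 alpha = alpha,
                 comparisons = do.call(rbind, rows)),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$f, x$p))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Build a condition-comparison report
#'
#' One row per comparison, shaped like the published statistics table:
#' for each metric and each experimental factor, factors with >= 3
#' condition levels get Tukey rows following one-way ANOVA; factors with
#' 2 levels get an unpaired Student's t-test row.
#'
#' @param data Long-format data.frame with columns `metric`, `condition`,
#'   `value` (one row per animal x metric).
#' @param factors Named list mapping factor name to the ordered character
#'   vector of its condition levels (e.g.
#'   `list(Osmo = c("control", "low", "high"))`).
#' @param alpha Significance level.
#' @return Data.frame with columns `figure` (metric), `description`
#'   (e.g. `"Osmo: control vs low"`), `method`, `estimate`, `ci_low`,
#'   `ci_high`, `significant`, `p_value`. Empty input gives an empty
#'   table with the same columns.
#' @export
build_report <- function(data, factors, alpha = 0.05) {
  template <- data.frame(figure = character(0), description = character(0),
                         method = character(0), estimate = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0),
                         significant = logical(0), p_value = numeric(0))
  if (is.null(data) || nrow(data) == 0L) return(template)
  stopifnot(all(c("metric", "condition", "value") %in% names(data)))
  out <- list()
  for (metric in unique(data$metric)) {
    sub <- data[data$metric == metric, , drop = FALSE]
    for (fac in names(factors)) {
      levels <- factors[[fac]]
      groups <- lapply(levels, function(l) sub$value[sub$condition == l])
      names(groups) <- levels
      groups <- groups[lengths(groups) >= 2L]
      if (length(groups) >= 3L) {
        cmp <- anova_tukey(groups, alpha = alpha)$comparisons
      } else if (length(groups) == 2L) {
        tt <- t_test_unpaired(groups[[1L]], groups[[2L]],
                              conf_level = 1 - alpha)
        cmp <- data.frame(
          description = paste(names(groups)[1L], "vs", names(groups)[2L]),
          method = "t_test", estimate = tt$estimate,
          ci_low = tt$ci_low, ci_high = tt$ci_high,
          significant = tt$p < alpha, p_value = tt$p)
      } else {
        next
      }
      cmp$description <- paste0(fac, ": ", cmp$description)
      cmp <- cbind(figure = metric, cmp)
      out[[length(out) + 1L]] <- cmp
    }
  }
  if (length(out) == 0L) return(template)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a comparison report as CSV
#'
#' @param report Data.frame from [build_report()].
#' @param path CSV path.
#' @return `read_report()` the data.frame; `write_report()` `path`,
#'   invisibly.
#' @export
write_report <- function(report, path) {
  df <- report
  for (col in c("estimate", "ci_low", "ci_high", "p_value")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("estimate", "ci_low", "ci_high", "p_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$significant <- as.logical(df$significant)
  df
}
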