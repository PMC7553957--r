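#' Pearson chi-square test on a contingency table
#'
#' Uncorrected by default: for a 2x2 table the statistic equals the
#' closed form n(ad - bc)^2 / (r1 r2 c1 c2). Yates continuity correction is
#' available as a sensitivity flag.
#'
#' @param counts a matrix (at least 2x2) of non-negative integer counts.
#' @param correction apply the Yates continuity correction (default
#'   \code{FALSE}).
#' @return an object of class \code{p53_test_result}: list with
#'   \code{statistic}, \code{df}, \code{p_value}, \code{method}.
#' @examples
#' pearson_chi2(matrix(c(28, 101, 50, 100), 2))
#' @export
pearson_chi2 <- function(counts, correction = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || nrow(counts) < 2L || ncol(counts) < 2L)
    stop("counts must be a non-negative matrix of at least 2x2",
         call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin: the chi-square statistic is undefined; ",
         "use fisher_exact()", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correction))
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              if (correction) "pearson_chi2_yates" else "pearson_chi2")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p-value from the hypergeometric distribution; companion
#' for tables with small or zero margins where the chi-square approximation
#' breaks down.
#'
#' @param counts a 2x2 matrix of non-negative integer counts.
#' @return a \code{p53_test_result} (statistic is the sample odds ratio
#'   estimate; \code{df} is \code{NA}).
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L)) || any(counts < 0))
    stop("fisher_exact expects a non-negative 2x2 table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  ht <- stats::fisher.test(counts, alternative = "two.sided")
  test_result(unname(ht$estimate), NA_integer_, ht$p.value, "fisher_exact")
}

#' Non-parametric rank tests
#'
#' Mann-Whitney (two groups), Kruskal-Wallis (two or more groups) and
#' Spearman rank correlation (paired vectors), with midrank tie handling.
#'
#' @param method one of \code{"mann_whitney"}, \code{"kruskal_wallis"},
#'   \code{"spearman"}.
#' @param values numeric vector (the first paired vector for
#'   \code{spearman}).
#' @param groups grouping vector (ignored for \code{spearman}).
#' @param y second paired vector (\code{spearman} only).
#' @return a \code{p53_test_result}; for \code{spearman} the statistic is
#'   the rank-correlation coefficient rho.
#' @export
rank_test <- function(method = c("mann_whitney", "kruskal_wallis",
                                 "spearman"),
                      values, groups = NULL, y = NULL) {
  method <- match.arg(method)
  if (method == "spearman") {
    if (is.null(y) || length(y) != length(values))
      stop("spearman needs paired vectors of equal length", call. = FALSE)
    ok <- stats::complete.cases(values, y)
    ht <- suppressWarnings(
      stats::cor.test(values[ok], y[ok], method = "spearman",
                      exact = FALSE))
    return(test_result(unname(ht$estimate), NA_integer_, ht$p.value,
                       "spearman"))
  }
  if (is.null(groups) || length(groups) != length(values))
    stop("group labels must match the values", call. = FALSE)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.factor(as.character(groups[ok]))
  if (nlevels(groups) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  if (method == "mann_whitney") {
    if (nlevels(groups) != 2L)
      stop("mann_whitney needs exactly 2 groups", call. = FALSE)
    ht <- suppressWarnings(
      stats::wilcox.test(values ~ groups, exact = FALSE, correct = FALSE))
    return(test_result(unname(ht$statistic), NA_integer_, ht$p.value,
                       "mann_whitney"))
  }
  ht <- stats::kruskal.test(values, groups)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value,
              "kruskal_wallis")
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, monotone and capped at 1, in the input order.
#' @examples
#' bonferroni_holm(c(0.01, 0.04, 0.03))
#' @export
bonferroni_holm <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Median split into high/low expression groups
#'
#' Values strictly above the median are \code{high}; values at or below the
#' median are \code{low} (ties at the median go to \code{low}, a fixed
#' documented policy); missing values stay unlabelled (\code{NA}).
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return character vector over \code{\{high, low, NA\}}.
#' @export
median_split <- function(values) {
  v <- as.numeric(values)
  ok <- !is.na(v)
  if (sum(ok) < 2L)
    stop("median_split needs at least 2 non-missing values", call. = FALSE)
  m <- stats::median(v[ok])
  if (all(v[ok] == m))
    warning("all values equal the median; every sample labelled 'low'",
            call. = FALSE)
  out <- rep(NA_character_, length(v))
  out[ok] <- ifelse(v[ok] > m, "high", "low")
  out
}

test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = as.numeric(statistic),
                 df = if (is.na(df)) NA_integer_ else as.integer(df),
                 p_value = as.numeric(p_value), method = method),
            class = "p53_test_result")
}

#' @export
print.p53_test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
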