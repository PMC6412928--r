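as_score_matrix <- function(m, min_cols = 2) {
  if (is.data.frame(m)) {
    m <- as.matrix(dplyr::select(m, dplyr::where(is.numeric)))
  }
  if (!is.matrix(m) || !is.numeric(m)) {
    abort("Expected a numeric matrix or a data frame with numeric columns.",
          class = "dietscore_stats_error")
  }
  if (anyNA(m)) {
    abort("Score matrix must not contain missing cells.",
          class = "dietscore_stats_error")
  }
  if (nrow(m) < 2 || ncol(m) < min_cols) {
    abort(sprintf("Need at least 2 rows and %d columns.", min_cols),
          class = "dietscore_stats_error")
  }
  m
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' Internal-consistency coefficient over item columns (here, typically the
#' sixteen nutrient subscores):
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)}
#' where \eqn{s_i^2} are item variances and \eqn{s_T^2} the variance of row
#' sums. The confidence interval uses Feldt's method:
#' \eqn{(1-\alpha)/(1-\hat\alpha)} follows an F distribution with
#' \eqn{n-1} and \eqn{(n-1)(k-1)} degrees of freedom.
#'
#' @param m Numeric matrix or data frame (rows = subjects, columns = items);
#'   non-numeric data-frame columns are dropped.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `dq_alpha`: list with `alpha`, `conf_low`,
#'   `conf_high`, `conf_level`, `n`, `k`. Has [tidy()] and [glance()]
#'   methods.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
#' cronbach_alpha(m)$alpha  # 8/9
cronbach_alpha <- function(m, conf_level = 0.95) {
  m <- as_score_matrix(m)
  k <- ncol(m); n <- nrow(m)
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    abort("Total-score variance is zero; alpha is undefined.",
          class = "dietscore_stats_error")
  }
  item_var <- apply(m, 2, var)
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- (1 - conf_level) / 2
  conf_low <- 1 - (1 - alpha) * qf(1 - p, df1, df2)
  conf_high <- 1 - (1 - alpha) * qf(p, df1, df2)
  structure(
    list(alpha = alpha, conf_low = conf_low, conf_high = conf_high,
         conf_level = conf_level, n = n, k = k),
    class = "dq_alpha"
  )
}

#' @export
print.dq_alpha <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f  (%g%% CI %.3f-%.3f; n = %d, k = %d)\n",
              x$alpha, 100 * x$conf_level, x$conf_low, x$conf_high, x$n, x$k))
  invisible(x)
}

#' @method tidy dq_alpha
#' @export
tidy.dq_alpha <- function(x, ...) {
  tibble::tibble(estimate = x$alpha, conf.low = x$conf_low,
                 conf.high = x$conf_high)
}

#' @method glance dq_alpha
#' @export
glance.dq_alpha <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, conf.low = x$conf_low,
                 conf.high = x$conf_high, conf.level = x$conf_level,
                 n = x$n, k = x$k)
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement between two measurements of the same quantity:
#' bias is the mean of `a - b`, the limits of agreement are
#' `bias +/- 1.96 x SD` of the differences, and `pct_within` is the
#' percentage of pairs falling inside the limits. When comparing a 0-1 score
#' with a 0-100 one, rescale first (the difference direction and scale are
#' the caller's to fix and report).
#'
#' @param a,b Numeric vectors of equal length (>= 2). Differences are `a - b`.
#' @return An object of class `dq_bland_altman`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `pct_within`, `n`, and the per-pair `data`
#'   (means and differences). Has [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' ba <- bland_altman(c(50, 60, 70), c(45, 55, 68))
#' glance(ba)
bland_altman <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    abort("`a` and `b` must be numeric vectors of equal length.",
          class = "dietscore_stats_error")
  }
  if (length(a) < 2) {
    abort("Need at least 2 pairs.", class = "dietscore_stats_error")
  }
  if (anyNA(a) || anyNA(b)) {
    abort("Missing values are not allowed.", class = "dietscore_stats_error")
  }
  d <- a - b
  bias <- mean(d)
  sd_diff <- sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  pct_within <- 100 * mean(d >= loa_low & d <= loa_high)
  structure(
    list(bias = bias, sd_diff = sd_diff, loa_low = loa_low,
         loa_high = loa_high, pct_within = pct_within, n = length(a),
         data = tibble::tibble(mean = (a + b) / 2, diff = d)),
    class = "dq_bland_altman"
  )
}

#' @export
print.dq_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f, limits of agreement [%.3f, %.3f], %.2f%% of %d pairs within\n",
    x$bias, x$loa_low, x$loa_high, x$pct_within, x$n
  ))
  invisible(x)
}

#' @method tidy dq_bland_altman
#' @export
tidy.dq_bland_altman <- function(x, ...) x$data

#' @method glance dq_bland_altman
#' @export
glance.dq_bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, loa_low = x$loa_low,
                 loa_high = x$loa_high, pct_within = x$pct_within, n = x$n)
}

#' Quantile stratification with rank-based group comparison
#'
#' Bins observations into `k` quantile groups of `by` (tertiles, quartiles,
#' ...) and compares the distribution of `values` across groups with a
#' Kruskal-Wallis omnibus test. Ties in `by` are resolved by average rank,
#' then stable original order, so group assignment is reproducible.
#'
#' @param values Numeric vector to compare across strata.
#' @param by Numeric vector defining the strata (e.g. another diet score).
#' @param k Number of quantile groups, >= 2.
#' @return An object of class `dq_strata`: `groups` (tibble with `group`,
#'   `n`, `mean`, `by_min`, `by_max`), `p_value`, `k`, and the per-row
#'   assignment in `data`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(90); y <- x + rnorm(90, sd = 0.2)
#' stratify_and_compare(y, x, k = 3)
stratify_and_compare <- function(values, by, k = 3) {
  if (!is.numeric(values) || !is.numeric(by) || length(values) != length(by)) {
    abort("`values` and `by` must be aligned numeric vectors.",
          class = "dietscore_stats_error")
  }
  if (k < 2 || length(values) < k) {
    abort("Need k >= 2 and at least k observations.",
          class = "dietscore_stats_error")
  }
  if (length(unique(by)) < 2) {
    abort("`by` is degenerate (all values equal); cannot stratify.",
          class = "dietscore_stats_error")
  }
  r <- rank(by, ties.method = "average")
  group <- dplyr::ntile(r, k)  # ties in r fall back to stable row order
  dat <- tibble::tibble(values = values, by = by, group = group)
  groups <- dat |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$values),
                     by_min = min(.data$by), by_max = max(.data$by),
                     .groups = "drop")
  if (length(unique(values)) < 2) {
    # all values tied: no evidence of any group difference
    p_value <- 1; statistic <- 0
  } else {
    kw <- kruskal.test(values ~ factor(group))
    p_value <- kw$p.value; statistic <- unname(kw$statistic)
  }
  structure(
    list(groups = groups, p_value = p_value, statistic = statistic,
         k = k, data = dat),
    class = "dq_strata"
  )
}

#' @export
print.dq_strata <- function(x, ...) {
  cat(sprintf("Stratification into %d quantile groups (Kruskal-Wallis p = %.3g)\n",
              x$k, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @method tidy dq_strata
#' @export
tidy.dq_strata <- function(x, ...) x$groups

#' @method glance dq_strata
#' @export
glance.dq_strata <- function(x, ...) {
  tibble::tibble(k = x$k, statistic = x$statistic, p.value = x$p_value,
                 n = nrow(x$data))
}

#' Proportion of variance explained by principal components
#'
#' Eigen-decomposes the covariance matrix of the column-centered score
#' matrix (covariance, not correlation: subscores share the \[0, 1\] scale)
#' and returns the eigenvalues normalised to sum to one, in descending
#' order.
#'
#' @inheritParams cronbach_alpha
#' @return An object of class `dq_pca`: `proportions` (descending, summing
#'   to 1), `cumulative`, `sdev`, `n`, `k`. Has [tidy()] and
#'   [ggplot2::autoplot()] methods.
#' @export
#' @examples
#' set.seed(1)
#' pca_variance_explained(matrix(rnorm(200), ncol = 4))$proportions
pca_variance_explained <- function(m) {
  m <- as_score_matrix(m)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) {
    abort("Zero total variance; PCA undefined.",
          class = "dietscore_stats_error")
  }
  props <- ev / sum(ev)
  structure(
    list(proportions = props, cumulative = cumsum(props), sdev = pc$sdev,
         n = nrow(m), k = ncol(m)),
    class = "dq_pca"
  )
}

#' @export
print.dq_pca <- function(x, ...) {
  cat(sprintf("PCA over %d items (n = %d); variance explained:\n", x$k, x$n))
  print(round(x$proportions, 4))
  invisible(x)
}

#' @method tidy dq_pca
#' @export
tidy.dq_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$proportions),
                 proportion = x$proportions, cumulative = x$cumulative)
}
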