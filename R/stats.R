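# Rank-sum and linear-model statistics used for the size-fraction and
# regional contrasts.

# exact null distribution of the Mann-Whitney U statistic: number of
# configurations with U = k for sample sizes m, n, via the standard
# recursion c(k; m, n) = c(k - n; m - 1, n) + c(k; m, n - 1)
#' @noRd
u_counts <- function(m, n) {
  K <- m * n
  # tab[[mm + 1]] is the count vector over k = 0..K for (mm, nn) at current nn
  prev <- vector("list", m + 1L)
  for (mm in 0:m) prev[[mm + 1L]] <- c(1, rep(0, K))  # nn = 0: only k = 0
  for (nn in 1:n) {
    cur <- vector("list", m + 1L)
    cur[[1L]] <- c(1, rep(0, K))                      # mm = 0
    for (mm in 1:m) {
      shifted <- c(rep(0, nn), cur[[mm]][seq_len(K + 1L - nn)])
      cur[[mm + 1L]] <- shifted + prev[[mm + 1L]]
    }
    prev <- cur
  }
  prev[[m + 1L]]
}

#' @noRd
pwilcox_exact <- function(q, m, n, lower_tail = TRUE) {
  cnt <- u_counts(m, n)
  p <- cnt / choose(m + n, m)
  q <- floor(q)
  if (lower_tail) {
    if (q < 0) 0 else sum(p[seq_len(min(q, m * n) + 1L)])
  } else {
    if (q < 0) 1 else if (q >= m * n) 0 else sum(p[(q + 2L):(m * n + 1L)])
  }
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney U for the first sample. The exact null
#' distribution (computed by dynamic programming over the U-count recursion)
#' is used when both samples have at most `exact_max` observations and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param exact_max Largest per-group size for the exact path (default 25).
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   path; forcing `TRUE` with ties is an error.
#' @return List of class `contrast_result`: group labels and sizes, medians,
#'   `statistic` (U), `p_value`, `alternative = "two.sided"`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25L, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stopf("both groups must be nonempty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  ties <- table(r)
  has_ties <- any(ties > 1)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  use_exact <- if (is.null(exact)) (m <= exact_max && n <= exact_max && !has_ties)
               else exact
  if (use_exact && has_ties)
    stopf("exact p-value not available with ties")
  if (use_exact) {
    p <- if (U > m * n / 2) pwilcox_exact(U - 1, m, n, lower_tail = FALSE)
         else pwilcox_exact(U, m, n, lower_tail = TRUE)
    p <- min(2 * p, 1)
    method <- "exact"
  } else {
    z <- U - m * n / 2
    N <- m + n
    sigma <- sqrt((m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    if (sigma == 0) {
      # every observation identical: no evidence of any difference
      p <- 1
    } else {
      z <- (z - sign(z) * 0.5) / sigma
      p <- min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
    }
    method <- "normal approximation"
  }
  structure(list(group_a_label = deparse(substitute(x)),
                 group_b_label = deparse(substitute(y)),
                 n_a = m, n_b = n,
                 median_a = median(x), median_b = median(y),
                 statistic = U, p_value = p, alternative = "two.sided",
                 method = method),
            class = "contrast_result")
}

#' Simple linear regression with Pearson correlation
#'
#' Ordinary least squares of `y` on `x` in closed form, with adjusted
#' R-squared `1 - (1 - R2)(n - 1)/(n - 2)`, the Pearson correlation and its
#' two-sided p-value from the t distribution on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, `x` non-constant).
#' @return List of class `fit_result`: slope, intercept, r2, adjusted_r2,
#'   pearson_r, p_value, n.
#' @export
linear_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stopf("x is constant; slope undefined")
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  r2 <- r^2
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r2))
    2 * pt(-abs(tt), df = n - 2)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 adjusted_r2 = adj, pearson_r = r, p_value = p, n = n),
            class = "fit_result")
}

#' Run metadata-defined group contrasts over an abundance table
#'
#' Each contrast names a metric (and optionally a scope) from the abundance
#' table and two disjoint sample groups as metadata predicates on the sample
#' sheet (every named field must match one of the listed values). The
#' contrast is a two-sided rank-sum test of the per-sample metric values;
#' group medians are reported alongside.
#'
#' @param abundance Tidy table from [abundance_table()].
#' @param samples Sample sheet.
#' @param contrasts List of contrast specs; each is a list with elements
#'   `name`, `metric`, optionally `scope`/`scope_label`, and `group_a`,
#'   `group_b` — named lists of metadata values, e.g.
#'   `list(fraction = "small", molecule = "DNA")`.
#' @return Data.frame, one row per contrast: names, group sizes, medians,
#'   U statistic and p-value.
#' @export
run_contrasts <- function(abundance, samples, contrasts) {
  pick <- function(pred) {
    sel <- rep(TRUE, nrow(samples))
    for (f in names(pred)) sel <- sel & samples[[f]] %in% pred[[f]]
    samples$sample_id[sel]
  }
  rows <- list()
  if (length(contrasts) == 0L)
    return(data.frame(contrast = character(0), metric = character(0),
                      scope_label = character(0), n_a = integer(0),
                      n_b = integer(0), median_a = numeric(0),
                      median_b = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), method = character(0),
                      stringsAsFactors = FALSE))
  for (ct in contrasts) {
    a_ids <- pick(ct$group_a); b_ids <- pick(ct$group_b)
    if (length(a_ids) == 0L)
      stopf("contrast '%s': group_a predicate matches no samples", ct$name %||% "?")
    if (length(b_ids) == 0L)
      stopf("contrast '%s': group_b predicate matches no samples", ct$name %||% "?")
    ab <- abundance[abundance$metric == ct$metric, , drop = FALSE]
    if (!is.null(ct$scope_label))
      ab <- ab[ab$scope_label == ct$scope_label, , drop = FALSE]
    va <- ab$value[ab$sample_id %in% a_ids]
    vb <- ab$value[ab$sample_id %in% b_ids]
    if (length(va) == 0L || length(vb) == 0L)
      stopf("contrast '%s': no abundance values for a group", ct$name %||% "?")
    w <- wilcoxon_rank_sum(va, vb)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = ct$name %||% ct$metric, metric = ct$metric,
      scope_label = ct$scope_label %||% "all",
      n_a = w$n_a, n_b = w$n_b, median_a = w$median_a, median_b = w$median_b,
      statistic = w$statistic, p_value = w$p_value, method = w$method,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
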