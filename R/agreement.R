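#' Range-normalised root mean square error
#'
#' RMSE of `predicted` against `reference`, divided by the range of the
#' reference values and expressed in percent — the normalisation used for
#' all method-comparison errors in this package.
#'
#' @param reference reference measurements (the normalising range is taken
#'   from this vector).
#' @param predicted predictions/measurements to compare, same length.
#' @return NRMSE in percent.
#' @examples
#' nrmse(c(0, 100), c(10, 110))  # RMSE 10 over range 100 -> 10%
#' @export
nrmse <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted), length(reference) >= 2)
  rng <- diff(range(reference))
  if (rng <= 0) stop("zero reference range: NRMSE is undefined")
  100 * sqrt(mean((predicted - reference)^2)) / rng
}

#' Ordinary least-squares line between two measurement vectors
#'
#' Fits `y ~ x` by OLS (via [stats::lm()]) and also reports the
#' through-origin slope, since method-comparison regressions are sometimes
#' forced through zero.
#'
#' @param x predictor vector (`n >= 3`, non-degenerate).
#' @param y response vector.
#' @return list with `slope`, `intercept`, `r_squared` and `slope_origin`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) <= 0) stop("degenerate x: zero variance")
  fit <- lm(y ~ x)
  fit0 <- lm(y ~ x + 0)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = cor(x, y)^2,
       slope_origin = unname(coef(fit0)[1]))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that validates the inputs the way the
#' package's agreement analyses require.
#'
#' @param x,y numeric vectors (`n >= 3`, positive variances).
#' @return the correlation coefficient `r`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) <= 0 || var(y) <= 0) stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b`, their mean (the bias) and the limits of
#' agreement `bias +/- 1.96 SD(d)` (sample SD, n-1 denominator).
#'
#' @param a,b paired measurement vectors of equal length (`>= 2`).
#' @return object of class `bland_altman`: list with `bias`, `sd_diff`,
#'   `loa` (length-2), `differences` and `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  stopifnot(length(a) >= 2)
  d <- a - b
  s <- if (length(d) >= 2) sd(d) else 0
  if (is.na(s)) s <- 0
  structure(list(bias = mean(d), sd_diff = s,
                 loa = mean(d) + c(-1.96, 1.96) * s,
                 differences = d, means = (a + b) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, SD %.3f, LoA [%.3f, %.3f] (n = %d)\n",
              x$bias, x$sd_diff, x$loa[1], x$loa[2], length(x$differences)))
  invisible(x)
}

#' Method-agreement analysis between a candidate and a reference method
#'
#' The central comparison "fit" of the package: given paired measurements
#' by a reference method (e.g. optical leaf area) and a candidate method
#' (e.g. volumetric leaf area), computes the OLS line of candidate on
#' reference, the Pearson correlation, the RMSE and range-normalised RMSE
#' (percent of the reference range), and the Bland-Altman bias and limits
#' of agreement of `candidate - reference`.
#'
#' @param reference reference-method measurements.
#' @param candidate candidate-method measurements, same length (`n >= 3`).
#' @param labels length-2 character: names of the reference and candidate
#'   methods, used in printing and plotting.
#' @return object of class `method_agreement` with components `n`, `slope`,
#'   `intercept`, `slope_origin`, `pearson_r`, `rmse`, `nrmse_pct`, `bias`,
#'   `loa_low`, `loa_high`, `ba` (the [bland_altman()] object) and `data`.
#' @seealso [coef.method_agreement()], [plot.method_agreement()]
#' @export
method_agreement <- function(reference, candidate,
                             labels = c("reference", "candidate")) {
  stopifnot(length(reference) == length(candidate), length(reference) >= 3)
  fit <- linear_fit(reference, candidate)
  ba <- bland_altman(candidate, reference)
  structure(list(
    n = length(reference),
    slope = fit$slope, intercept = fit$intercept,
    slope_origin = fit$slope_origin,
    r_squared = fit$r_squared,
    pearson_r = pearson(reference, candidate),
    rmse = sqrt(mean((candidate - reference)^2)),
    nrmse_pct = nrmse(reference, candidate),
    bias = ba$bias, loa_low = ba$loa[1], loa_high = ba$loa[2],
    ba = ba, labels = labels,
    data = data.frame(reference = reference, candidate = candidate)),
    class = "method_agreement")
}

#' @export
print.method_agreement <- function(x, ...) {
  cat(sprintf("Method agreement: %s vs %s (n = %d)\n",
              x$labels[2], x$labels[1], x$n))
  cat(sprintf("  OLS: slope %.4f, intercept %.3f (through origin: %.4f), r = %.4f\n",
              x$slope, x$intercept, x$slope_origin, x$pearson_r))
  cat(sprintf("  NRMSE %.3f%% of the %s range (RMSE %.3f)\n",
              x$nrmse_pct, x$labels[1], x$rmse))
  cat(sprintf("  Bland-Altman: bias %.3f, LoA [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
summary.method_agreement <- function(object, ...) {
  out <- with(object, data.frame(
    n = n, slope = slope, intercept = intercept,
    slope_origin = slope_origin, pearson_r = pearson_r, rmse = rmse,
    nrmse_pct = nrmse_pct, bias = bias, loa_low = loa_low,
    loa_high = loa_high))
  rownames(out) <- NULL
  out
}

#' @export
coef.method_agreement <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.method_agreement <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$reference else newdata
  object$intercept + object$slope * x
}

#' @export
residuals.method_agreement <- function(object, ...) {
  object$data$candidate - predict(object)
}

#' Diagnostic plots for a method-agreement analysis
#'
#' Two panels: candidate-versus-reference scatter with the identity and the
#' fitted OLS line, and the Bland-Altman plot (differences against pair
#' means, with bias and limits of agreement).
#'
#' @param x a [method_agreement()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.method_agreement <- function(x, ...) {
  old <- par(mfrow = c(1, 2))
  on.exit(par(old))
  plot(x$data$reference, x$data$candidate,
       xlab = x$labels[1], ylab = x$labels[2], ...)
  abline(0, 1, lty = 2)
  abline(x$intercept, x$slope, col = 2)
  legend("topleft", bty = "n",
         legend = c("identity", sprintf("OLS slope %.3f", x$slope)),
         lty = c(2, 1), col = c(1, 2))
  plot(x$ba$means, x$ba$differences,
       xlab = sprintf("mean of %s and %s", x$labels[1], x$labels[2]),
       ylab = sprintf("%s - %s", x$labels[2], x$labels[1]), ...)
  abline(h = x$bias, col = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Coefficient-of-variation table of grouped dimension records
#'
#' Per group (e.g. sampling date) and per dimension column, the coefficient
#' of variation `100 * SD / mean` (sample SD, n-1). Two summary rows are
#' appended: `Mean`, the column-wise mean of the group CVs, and `Season`,
#' the CV of the pooled data across all groups (computed on the raw data,
#' not by averaging group CVs).
#'
#' @param data data.frame of measurements.
#' @param group name of the grouping column.
#' @param dims names of the dimension columns (default: all numeric columns
#'   except the group).
#' @return data.frame of class `cv_table` (CVs in percent).
#' @export
cv_table <- function(data, group, dims = NULL) {
  stopifnot(group %in% names(data))
  if (is.null(dims)) {
    dims <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], group)
  }
  g <- factor(data[[group]], levels = unique(data[[group]]))
  if (any(table(g) < 2)) stop("each group needs at least 2 records")
  cv1 <- function(x) {
    m <- mean(x)
    if (m == 0) stop("zero group mean: CV undefined")
    100 * sd(x) / m
  }
  per_group <- matrix(NA_real_, nlevels(g), length(dims),
                      dimnames = list(levels(g), dims))
  for (lev in levels(g)) {
    for (d in dims) per_group[lev, d] <- cv1(data[[d]][g == lev])
  }
  out <- rbind(per_group,
               Mean = colMeans(per_group),
               Season = vapply(dims, function(d) cv1(data[[d]]), numeric(1)))
  out <- as.data.frame(out)
  class(out) <- c("cv_table", "data.frame")
  out
}

#' Pairwise Pearson correlation matrix with significance classes
#'
#' Pairwise correlations among dimension columns with two-sided t-test
#' p-values; correlations with `0.001 < P < 0.05` are flagged `*` and those
#' with `P < 0.001` are flagged `**`. No multiple-testing correction is
#' applied.
#'
#' @param data data.frame (numeric columns are used; `n >= 3` rows).
#' @return object of class `correlation_matrix`: list of matrices `r`, `p`
#'   and character `stars`.
#' @export
correlation_matrix <- function(data) {
  num <- data[vapply(data, is.numeric, TRUE)]
  stopifnot(nrow(num) >= 3, ncol(num) >= 2)
  if (any(vapply(num, var, numeric(1)) <= 0)) {
    stop("constant column: correlation undefined")
  }
  k <- ncol(num)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(num), names(num)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ct <- cor.test(num[[i]], num[[j]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[p < 0.05 & p > 0.001] <- "*"
  stars[p <= 0.001] <- "**"
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  k <- ncol(x$r)
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars), k, k,
                 dimnames = dimnames(x$r))
  diag(disp) <- "1"
  disp[upper.tri(disp)] <- ""
  print(as.data.frame(disp), right = TRUE)
  cat("Significance: * 0.001 < P < 0.05, ** P <= 0.001 (two-sided)\n")
  invisible(x)
}
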