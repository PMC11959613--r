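#' @include AllClasses.R
NULL

#' Boxplot five-number summary
#'
#' Median and quartiles (linear interpolation between order statistics,
#' \code{\link[stats]{quantile}} type 7) with Tukey whiskers: the smallest
#' and largest data values within 1.5 times the interquartile range beyond
#' the quartiles; values outside are listed as outliers.
#'
#' @param values numeric vector (NA dropped), length >= 1.
#' @param label optional group label.
#' @return list with \code{label}, \code{n}, \code{median}, \code{q1},
#'   \code{q3}, \code{whiskerLow}, \code{whiskerHigh}, \code{outliers}.
#' @examples
#' summarizeBox(1:9)
#' @export
summarizeBox <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  if (!length(values)) paramError("no values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  inLow <- values[values >= q[1] - 1.5 * iqr]
  inHigh <- values[values <= q[3] + 1.5 * iqr]
  list(label = label, n = length(values),
       median = q[2], q1 = q[1], q3 = q[3],
       whiskerLow = min(inLow), whiskerHigh = max(inHigh),
       outliers = sort(values[values < q[1] - 1.5 * iqr |
                              values > q[3] + 1.5 * iqr]))
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Fits a one-way ANOVA across labelled groups and reports the F statistic,
#' its p-value and Tukey honest-significant-difference adjusted p-values
#' for every group pair (studentized-range distribution).
#'
#' @param values numeric vector of observations.
#' @param groups group labels (coerced to factor), same length.
#' @return list with \code{F}, \code{p} and \code{pairwise}: a data.frame
#'   of group pairs with mean difference and adjusted p.
#' @examples
#' anovaTukey(c(rnorm(10), rnorm(10, 3)), rep(c("a", "b"), each = 10))
#' @export
anovaTukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) paramError("need >= 2 groups")
  if (any(table(groups) < 2)) paramError("each group needs n >= 2")
  if (sd(values) == 0)
    stop("all values identical: F statistic undefined")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       pairwise = data.frame(pair = rownames(hsd),
                             diff = hsd[, "diff"],
                             pAdj = hsd[, "p adj"],
                             row.names = NULL))
}
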