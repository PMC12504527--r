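# Statistical procedures applied to the quantified outputs: trial
# blocking, t-tests, one-way ANOVA with Tukey HSD, and p-value
# adjustments.

#' Average trial errors into consecutive blocks
#'
#' Maze errors from consecutive trials are averaged in non-overlapping,
#' ordered blocks (default 3 trials per block). The trial count must be
#' divisible by the block size.
#'
#' @param trials ordered numeric vector of per-trial error counts.
#' @param block_size trials per block (default 3).
#' @return Numeric vector of block means, in order.
#' @examples
#' block_average_errors(c(0, 0, 0, 6, 6, 6)) # 0, 6
#' @export
block_average_errors <- function(trials, block_size = 3L) {
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1")
  n <- length(trials)
  if (n == 0L || n %% block_size != 0L)
    stop(sprintf("%d trials cannot be split into blocks of %d", n, block_size))
  as.vector(tapply(trials, rep(seq_len(n %/% block_size), each = block_size),
                   mean))
}

#' Two-sample t-test (Student or Welch), two-sided
#'
#' Thin wrapper around [stats::t.test()] pinning the variants used for
#' group comparisons: classical Student (pooled variance) or Welch with
#' Welch-Satterthwaite fractional degrees of freedom. Always two-sided.
#'
#' @param x,y numeric samples, each with at least 2 values.
#' @param variant `"student"` or `"welch"`.
#' @return A one-row data frame: `statistic`, `df`, `p_value`, `variant`.
#' @examples
#' t_test(c(1, 2, 3), c(2, 3, 4), variant = "welch")
#' @export
t_test <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values")
  ht <- t.test(x, y, var.equal = (variant == "student"),
               alternative = "two.sided")
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p_value = ht$p.value, variant = variant)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus F test across k groups (df k-1, N-k) via [stats::aov()],
#' followed by all pairwise Tukey honestly-significant-difference
#' comparisons with adjusted p-values from the studentized range
#' distribution ([stats::TukeyHSD()]).
#'
#' @param groups named (or unnamed) list of numeric samples, each n >= 2.
#' @return A list: `anova` (one-row data frame with `F`, `df1`, `df2`,
#'   `p_value`) and `tukey` (data frame of pairwise comparisons with
#'   `diff`, `lwr`, `upr`, `p_adj`).
#' @export
oneway_anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  )
  fit <- aov(value ~ group, data = dat)
  tab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(
    anova = data.frame(F = tab["group", "F value"],
                       df1 = tab["group", "Df"],
                       df2 = tab["Residuals", "Df"],
                       p_value = tab["group", "Pr(>F)"]),
    tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  )
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m`, clipped to 1, with `m` the family size
#' (default: the number of p-values given).
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m family size (default `length(p_values)`).
#' @return Adjusted p-values, same length and order.
#' @examples
#' sidak_adjust(c(0.05, 0.2)) # 0.0975, 0.36
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  pmin(1, 1 - (1 - p_values)^m)
}

#' Holm step-down adjustment
#'
#' Step-down Holm correction with monotonicity enforcement, delegated to
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04)) # 0.02, 0.04
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}
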