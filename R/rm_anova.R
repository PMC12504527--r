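# Two-way repeated-measures (mixed-design) ANOVA: one between-subjects
# factor, one within-subjects factor, Greenhouse-Geisser sphericity
# correction, and Sidak-adjusted per-level group comparisons. Sums of
# squares are computed directly from cell means (complete balanced
# within-subject data; group sizes may differ), which keeps the
# computation transparent and fast enough for simulation studies.

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Mixed-design ANOVA for a complete design: every subject (animal)
#' measured once at every level of the within factor (block/timepoint),
#' subjects nested in a between factor (treatment group). The sum-of-squares
#' partition is
#' between-subjects = group + subjects-within-group, and
#' within-subjects = level + group:level + level:subjects residual.
#' F for the group effect uses the subjects-within-group mean square; F for
#' level and the interaction use the residual mean square, with
#' Greenhouse-Geisser epsilon multiplying their numerator and denominator
#' df (fractional df, as statistics software reports them). Epsilon is
#' computed from the pooled within-group covariance of the repeated
#' measures. With 2 within levels epsilon is exactly 1. Missing cells are
#' an error: no imputation.
#'
#' When the between factor has exactly 2 groups, per-level two-sample
#' Student t comparisons are reported with Sidak adjustment over the
#' within levels.
#'
#' @param data long-format data frame.
#' @param value,subject,between,within column names (defaults `"value"`,
#'   `"animal_id"`, `"group"`, `"level"`).
#' @return A list of class `rm_anova`: `effects` (data frame with effect,
#'   df1, df2, F, p_value; corrected fractional df for within-subject
#'   effects), `epsilon_gg`, and `comparisons` (per-level Sidak-adjusted
#'   group contrasts, or `NULL` when the between factor is not 2 groups).
#' @export
rm_anova_two_way <- function(data, value = "value", subject = "animal_id",
                             between = "group", within = "level") {
  for (cn in c(value, subject, between, within))
    if (!cn %in% names(data)) stop(sprintf("column '%s' not found", cn))
  y <- as.numeric(data[[value]])
  subj <- factor(data[[subject]])
  grp <- factor(data[[between]])
  lev <- factor(data[[within]])
  if (anyNA(y)) stop("missing values are not supported: no imputation")
  k <- nlevels(lev); a <- nlevels(grp); N <- nlevels(subj)
  if (k < 2L) stop("the within factor needs at least 2 levels")
  if (a < 2L) stop("the between factor needs at least 2 groups")
  tab <- table(subj, lev)
  if (any(tab != 1L))
    stop("incomplete design: every subject must be measured exactly once at every within level")
  sg <- tapply(as.integer(grp), subj, function(g) {
    u <- unique(g); if (length(u) != 1L) stop("a subject appears in more than one group"); u
  })
  subj_group <- factor(levels(grp)[sg], levels = levels(grp))
  n_g <- as.vector(table(subj_group))
  if (any(n_g < 2L)) stop("every group needs at least 2 subjects")

  # subject x level response matrix
  Y <- matrix(NA_real_, N, k, dimnames = list(levels(subj), levels(lev)))
  Y[cbind(as.integer(subj), as.integer(lev))] <- y
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  grp_means <- tapply(subj_means, subj_group, mean)        # per-group mean
  lev_means <- colMeans(Y)                                 # weighted over all subjects
  cell_means <- apply(Y, 2, function(col) tapply(col, subj_group, mean))
  cell_means <- matrix(cell_means, nrow = a)               # a x k

  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(n_g * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_level <- N * sum((lev_means - grand)^2)
  ss_cells <- sum(sweep((cell_means - grand)^2, 1, n_g, `*`))
  ss_interaction <- ss_cells - ss_group - ss_level
  ss_total <- sum((Y - grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_level - ss_interaction

  df_group <- a - 1; df_subj <- N - a
  df_level <- k - 1; df_inter <- (a - 1) * (k - 1)
  df_resid <- (N - a) * (k - 1)

  ms <- function(ss, df) ss / df
  F_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_subj)
  F_level <- ms(ss_level, df_level) / ms(ss_resid, df_resid)
  F_inter <- ms(ss_interaction, df_inter) / ms(ss_resid, df_resid)

  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  eps <- gg_epsilon(Y, subj_group)

  p_group <- pf(F_group, df_group, df_subj, lower.tail = FALSE)
  p_level <- pf(F_level, df_level * eps, df_resid * eps, lower.tail = FALSE)
  p_inter <- pf(F_inter, df_inter * eps, df_resid * eps, lower.tail = FALSE)

  effects <- data.frame(
    effect = c(between, within, paste0(between, ":", within)),
    df1 = c(df_group, df_level * eps, df_inter * eps),
    df2 = c(df_subj, df_resid * eps, df_resid * eps),
    F = c(F_group, F_level, F_inter),
    p_value = c(p_group, p_level, p_inter)
  )

  comparisons <- NULL
  if (a == 2L) {
    g1 <- levels(grp)[1]; g2 <- levels(grp)[2]
    raw <- vapply(seq_len(k), function(j) {
      t.test(Y[subj_group == g1, j], Y[subj_group == g2, j],
             var.equal = TRUE)$p.value
    }, numeric(1))
    comparisons <- data.frame(
      level = levels(lev),
      mean_diff = cell_means[1, ] - cell_means[2, ],
      p_value = raw,
      p_sidak = sidak_adjust(raw, m = k)
    )
  }

  structure(list(effects = effects, epsilon_gg = eps,
                 comparisons = comparisons,
                 n_subjects = N, n_groups = a, n_levels = k),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon: pooled (group-mean-centered) covariance S of
# the k repeated measures, double-centered to C; eps = tr(C)^2 /
# ((k-1) * sum(C^2)), bounded in [1/(k-1), 1].
gg_epsilon <- function(Y, subj_group) {
  k <- ncol(Y)
  centered <- Y
  for (g in levels(subj_group)) {
    idx <- subj_group == g
    centered[idx, ] <- sweep(Y[idx, , drop = FALSE], 2,
                             colMeans(Y[idx, , drop = FALSE]))
  }
  S <- crossprod(centered) / (nrow(Y) - nlevels(subj_group))
  C <- sweep(S, 1, rowMeans(S))
  C <- sweep(C, 2, colMeans(S))
  C <- C + mean(S)
  eps <- sum(diag(C))^2 / ((k - 1) * sum(C^2))
  min(1, max(1 / (k - 1), eps))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%d subjects, %d groups x %d levels)\n",
              x$n_subjects, x$n_groups, x$n_levels))
  cat(sprintf("Greenhouse-Geisser epsilon: %.4f\n", x$epsilon_gg))
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-14s F(%.4g, %.4g) = %.4f, p = %.4g\n", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$F[i], eff$p_value[i]))
  if (!is.null(x$comparisons)) {
    cat("Sidak-adjusted per-level group comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
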