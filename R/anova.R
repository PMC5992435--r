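#' Two-way fixed-effects ANOVA over run summaries
#'
#' Fits `dv ~ RTC * Diversity` on a balanced design of run summaries and
#' reports, per effect, the F statistic, degrees of freedom, p value and
#' classical eta-squared (`SS_effect / SS_total`), together with cell and
#' marginal means/SDs and Tukey HSD post-hoc comparisons for both main
#' effects. For a 3 x 3 design with r replicates the degrees of freedom are
#' 2, 2, 4 and 9(r - 1).
#'
#' @param design A `margin_design` or data frame with `rtc_level`,
#'   `diversity_level` and the `dv` column.
#' @param dv Name of the dependent-variable column (see [analyzed_dvs()]).
#' @return A `margin_anova` list: `dv`, `effects` (data frame with rows RTC,
#'   Diversity, `RTC:Diversity`: `df`, `df_den`, `sum_sq`, `F`, `p`, `eta_sq`),
#'   `ss_total`, `cell_means`, `marginal` (per-factor means/SDs), `posthoc`
#'   (per-factor Tukey tables, see [posthoc_pairwise()]), `n_per_cell`.
#' @export
two_way_anova <- function(design, dv) {
  d <- as.data.frame(design)
  stopifnot(all(c("rtc_level", "diversity_level") %in% names(d)))
  if (!dv %in% names(d)) stop("no column '", dv, "' in the design table")
  d$rtc <- factor(d$rtc_level,
                  levels = intersect(condition_levels(), unique(d$rtc_level)))
  d$div <- factor(d$diversity_level,
                  levels = intersect(condition_levels(),
                                     unique(d$diversity_level)))
  d$y <- d[[dv]]
  if (any(is.na(d$y))) stop("dependent variable contains NA")
  counts <- table(d$rtc, d$div)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("unbalanced design: unequal replicate counts per cell")
  }
  r <- as.vector(counts)[1L]
  if (r < 2L) stop("need >= 2 replicates per cell for the ANOVA")
  if (var(d$y) == 0) stop("degenerate input: zero total variance in ", dv)

  fit <- aov(y ~ rtc * div, data = d)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]
  ss_total <- sum(ss)
  df_den <- tab[["Df"]][4L]
  effects <- data.frame(
    effect = c("RTC", "Diversity", "RTC:Diversity"),
    df = as.integer(tab[["Df"]][1:3]),
    df_den = as.integer(df_den),
    sum_sq = ss[1:3],
    F = tab[["F value"]][1:3],
    p = tab[["Pr(>F)"]][1:3],
    eta_sq = ss[1:3] / ss_total)

  cell_means <- aggregate(y ~ rtc + div, data = d,
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
  cell_means <- data.frame(rtc = cell_means$rtc, diversity = cell_means$div,
                           mean = cell_means$y[, "mean"],
                           sd = cell_means$y[, "sd"])
  marginal <- list(
    RTC = data.frame(level = levels(d$rtc),
                     mean = tapply(d$y, d$rtc, mean),
                     sd = tapply(d$y, d$rtc, sd), row.names = NULL),
    Diversity = data.frame(level = levels(d$div),
                           mean = tapply(d$y, d$div, mean),
                           sd = tapply(d$y, d$div, sd), row.names = NULL))

  posthoc <- list(RTC = tukey_table(fit, "rtc"),
                  Diversity = tukey_table(fit, "div"))

  structure(list(dv = dv, effects = effects, ss_total = ss_total,
                 residual_ss = ss[4L], cell_means = cell_means,
                 marginal = marginal, posthoc = posthoc, n_per_cell = r),
            class = "margin_anova")
}

tukey_table <- function(fit, which) {
  tk <- TukeyHSD(fit, which = which)[[which]]
  lev <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(level_a = vapply(lev, `[`, "", 1L),
             level_b = vapply(lev, `[`, "", 2L),
             diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < 0.05,
             row.names = NULL)
}

#' Tukey HSD pairwise comparisons for one main effect
#'
#' All three level pairs of the chosen factor with mean difference,
#' Tukey-adjusted p value and a significance flag at alpha = 0.05.
#'
#' @inheritParams two_way_anova
#' @param factor `"RTC"` or `"Diversity"`.
#' @return Data frame with columns `level_a`, `level_b`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant`.
#' @export
posthoc_pairwise <- function(design, factor = c("RTC", "Diversity"), dv) {
  factor <- match.arg(factor)
  two_way_anova(design, dv)$posthoc[[factor]]
}

#' @export
print.margin_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Two-way ANOVA on %s (%d replicates per cell)\n", x$dv,
              x$n_per_cell))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-13s F(%d, %d) = %.*f, p = %.3g, eta^2 = %.*f\n",
                eff$effect[i], eff$df[i], eff$df_den[i], 2, eff$F[i],
                eff$p[i], 3, eff$eta_sq[i]))
  }
  cat("  Marginal means (RTC):      ",
      paste(sprintf("%s %.4f (SD %.4f)", x$marginal$RTC$level,
                    x$marginal$RTC$mean, x$marginal$RTC$sd), collapse = "; "),
      "\n")
  cat("  Marginal means (Diversity):",
      paste(sprintf("%s %.4f (SD %.4f)", x$marginal$Diversity$level,
                    x$marginal$Diversity$mean, x$marginal$Diversity$sd),
            collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.margin_anova <- function(object, ...) {
  print(object, ...)
  cat("  Tukey HSD (RTC):\n")
  print(object$posthoc$RTC, row.names = FALSE)
  cat("  Tukey HSD (Diversity):\n")
  print(object$posthoc$Diversity, row.names = FALSE)
  invisible(object)
}
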