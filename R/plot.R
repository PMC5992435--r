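#' Plot a run trajectory
#'
#' Simple line plot of one family of dependent variables over ticks.
#'
#' @param x A `margin_run` created with `trajectory = TRUE`.
#' @param which `"proportion"`, `"change"` or `"similarity"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.margin_run <- function(x, which = c("proportion", "change", "similarity"),
                            ...) {
  which <- match.arg(which)
  if (is.null(x$records)) stop("run was executed without trajectory = TRUE")
  prefix <- switch(which, proportion = "prop_", change = "change_",
                   similarity = "sim_")
  cols <- grep(paste0("^", prefix), names(x$records), value = TRUE)
  pal <- hcl.colors(length(cols), "Dark 3")
  matplot(x$records$tick, x$records[cols], type = "l", lty = 1, col = pal,
          xlab = "tick", ylab = which, ylim = c(0, 1),
          main = sprintf("RTC %s, Diversity %s", x$config$rtc_level,
                         x$config$diversity_level), ...)
  legend("topright", legend = sub(prefix, "", cols), col = pal, lty = 1,
         cex = 0.7, bty = "n")
  invisible(x)
}

#' Plot ANOVA cell means
#'
#' Cell means of the dependent variable by RTC level, one line per Diversity
#' level (a plain interaction plot).
#'
#' @param x A `margin_anova`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.margin_anova <- function(x, ...) {
  cm <- x$cell_means
  rtc_lev <- levels(cm$rtc)
  div_lev <- levels(cm$diversity)
  m <- matrix(NA_real_, length(rtc_lev), length(div_lev),
              dimnames = list(rtc_lev, div_lev))
  for (i in seq_len(nrow(cm))) {
    m[as.character(cm$rtc[i]), as.character(cm$diversity[i])] <- cm$mean[i]
  }
  pal <- hcl.colors(ncol(m), "Dark 3")
  matplot(seq_along(rtc_lev), m, type = "b", pch = 19, lty = 1, col = pal,
          xaxt = "n", xlab = "RTC", ylab = x$dv, main = x$dv, ...)
  axis(1, at = seq_along(rtc_lev), labels = rtc_lev)
  legend("topleft", legend = paste("Diversity", colnames(m)), col = pal,
         lty = 1, pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}
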