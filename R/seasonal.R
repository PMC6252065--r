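#' Seasonal comparison of sunrise/sunset offsets
#'
#' One-way ANOVA of the signed solar offsets (decimal hours) with season as
#' the explanatory variable, followed by Tukey HSD on all season pairs
#' (Tukey--Kramer under unequal group sizes). Seasons with fewer than two
#' observations are dropped with a warning; at least two groups must remain.
#' No normality or homoscedasticity gatekeeping is applied; per-group
#' summaries are returned for inspection.
#'
#' @param offsets numeric vector of signed offsets in decimal hours.
#' @param seasons factor or character vector of season labels, same length.
#' @param species optional species label for reporting.
#' @return a \code{seasonal_offset_test}: list with \code{species},
#'   \code{F}, \code{df} (c(between, within)), \code{p}, \code{tukey}
#'   (data.frame: pair, diff, lwr, upr, p_adj) and \code{groups}
#'   (data.frame: season, n, mean, sd).
#' @export
anova_offsets <- function(offsets, seasons, species = NULL) {
  stopifnot(length(offsets) == length(seasons))
  seasons <- as.character(seasons)
  tab <- table(seasons)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping season(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !seasons %in% small
    offsets <- offsets[keep]; seasons <- seasons[keep]
  }
  if (length(unique(seasons)) < 2)
    stop("need at least two seasons with >= 2 observations")
  season <- factor(seasons)
  fit <- stats::aov(offsets ~ season)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$season
  groups <- do.call(rbind, lapply(split(offsets, season), function(x)
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))))
  groups <- data.frame(season = rownames(groups), groups, row.names = NULL)
  structure(list(species = species %||% "",
                 F = s[["F value"]][1],
                 df = c(between = s[["Df"]][1], within = s[["Df"]][2]),
                 p = s[["Pr(>F)"]][1],
                 tukey = data.frame(pair = rownames(tk),
                                    diff = tk[, "diff"], lwr = tk[, "lwr"],
                                    upr = tk[, "upr"], p_adj = tk[, "p adj"],
                                    row.names = NULL),
                 groups = groups),
            class = "seasonal_offset_test")
}

#' @export
print.seasonal_offset_test <- function(x, ...) {
  cat(sprintf("<seasonal_offset_test>%s F(%d, %d) = %.2f, p = %.3g\n",
              if (nzchar(x$species)) paste0(" ", x$species) else "",
              x$df[1], x$df[2], x$F, x$p))
  print(x$tukey, digits = 3)
  invisible(x)
}
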