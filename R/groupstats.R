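#' Group comparison with a normality gate
#'
#' Compares two or more groups the way sleep-cohort statistics are usually
#' run: if every group passes the Shapiro-Wilk normality test at 0.05, a
#' one-way ANOVA is used, otherwise Kruskal-Wallis one-way analysis of
#' variance on ranks; multiple pairwise comparisons are Bonferroni-corrected
#' (pairwise t tests after ANOVA, pairwise Wilcoxon after Kruskal-Wallis).
#' For a paired two-group design a paired t test (or paired Wilcoxon, if the
#' differences fail the gate) is used instead.
#'
#' @param groups named list of numeric vectors, each of length >= 3
#' @param paired if TRUE (two groups of equal length only), use a paired test
#' @return a list with \code{method}, \code{statistic}, \code{p},
#'   \code{shapiroP} (per-group), and \code{pairwiseP} (Bonferroni-adjusted
#'   matrix, NULL for paired designs)
#' @export
groupComparison <- function(groups, paired = FALSE) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  n <- lengths(groups)
  if (any(n < 3)) stop("every group must have at least 3 observations")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  shapiroSafe <- function(x) {
    if (diff(range(x)) < .Machine$double.eps^0.5) return(0)
    shapiro.test(x)$p.value
  }
  if (paired) {
    if (length(groups) != 2 || n[1] != n[2])
      stop("paired comparison needs exactly 2 groups of equal length")
    d <- groups[[1]] - groups[[2]]
    sp <- shapiroSafe(d)
    if (sp > 0.05) {
      tt <- t.test(groups[[1]], groups[[2]], paired = TRUE)
      return(list(method = "paired t", statistic = unname(tt$statistic),
                  p = tt$p.value, shapiroP = c(differences = sp),
                  pairwiseP = NULL))
    }
    wt <- wilcox.test(groups[[1]], groups[[2]], paired = TRUE, exact = FALSE)
    return(list(method = "paired Wilcoxon", statistic = unname(wt$statistic),
                p = wt$p.value, shapiroP = c(differences = sp),
                pairwiseP = NULL))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), n), levels = names(groups))
  shapiroP <- vapply(groups, shapiroSafe, numeric(1))
  if (all(shapiroP > 0.05)) {
    fit <- aov(values ~ labels)
    an <- summary(fit)[[1]]
    pw <- pairwise.t.test(values, labels, p.adjust.method = "bonferroni",
                          pool.sd = TRUE)
    list(method = "one-way ANOVA", statistic = an[["F value"]][1],
         p = an[["Pr(>F)"]][1], shapiroP = shapiroP,
         pairwiseP = pw$p.value)
  } else {
    kw <- kruskal.test(values, labels)
    pw <- suppressWarnings(
      pairwise.wilcox.test(values, labels, p.adjust.method = "bonferroni",
                           exact = FALSE))
    list(method = "Kruskal-Wallis", statistic = unname(kw$statistic),
         p = kw$p.value, shapiroP = shapiroP, pairwiseP = pw$p.value)
  }
}
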