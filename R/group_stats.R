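#' Group summary: n, mean, SEM
#'
#' Neurons are the unit of replication; per-neuron scalar metrics are
#' summarized as mean +/- SEM with the sample standard deviation
#' (n - 1 denominator).
#'
#' @param values numeric vector, one value per neuron (NAs dropped).
#' @param label group label.
#' @return one-row data.frame: `group`, `n`, `mean`, `sd`, `sem` (NA when
#'   n = 1).
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarize")
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else NA_real_
  data.frame(group = label, n = n, mean = mean(values), sd = s,
             sem = s / sqrt(n))
}

#' Two-sample two-tailed t test
#'
#' Classic Student's t with pooled variance by default; Welch's unequal
#' variance form is available because group variances often differ across
#' phenotypes.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @param welch use the Welch correction instead of pooled variance.
#' @return list with `t`, `df`, `p`.
#' @export
ttest2 <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("ttest2 needs at least 2 values per group")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param groups named list of at least 3 numeric vectors (each n >= 2).
#' @return list with `F`, `df` (c(between, within)), `p`, and `tukey`: a
#'   data.frame of all pairwise comparisons (`comparison`, `diff`, `lwr`,
#'   `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 3)
    stop("anova_tukey needs >= 3 groups; use ttest2 for two")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(F = tab[["F value"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]),
       p = tab[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL))
}
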