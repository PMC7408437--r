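# Marker-association tests: gene expression versus a binary status (t test)
# or an ordinal covariate such as tumor stage (one-way ANOVA), with the
# per-level summaries needed for error-bar style reporting.

#' Significance tier of a p-value
#'
#' The conventional star scheme with boundaries closed on the more
#' significant side: `*` for (0.05, 0.01], `**` for (0.01, 0.001], `***`
#' for (0.001, 0.0001], `>***` below 0.0001, `"ns"` above 0.05.
#'
#' @param p p-value(s) in \[0, 1\].
#' @export
significance_tier <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 1e-4) ">***"
    else if (pp <= 1e-3) "***"
    else if (pp <= 1e-2) "**"
    else if (pp <= 5e-2) "*"
    else "ns"
  }, character(1))
}

.level_summaries <- function(x, g) {
  data.frame(
    level = levels(g),
    n = as.vector(table(g)),
    mean = as.vector(tapply(x, g, mean)),
    sd = as.vector(tapply(x, g, stats::sd)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Association of one gene's expression with a binary status
#'
#' Two-sided t test (Welch by default) of expression between the two status
#' levels, with per-level mean/sd/n summaries.
#'
#' @param expr_gene numeric expression vector for one gene.
#' @param status binary status per sample (two levels, each n >= 2).
#' @param gene,grouping optional names recorded in the result.
#' @param pooled classical pooled-variance statistic instead of Welch.
#' @return object of class `association_result`.
#' @export
binary_association <- function(expr_gene, status, gene = NA_character_,
                               grouping = "status", pooled = FALSE) {
  g <- factor(status)
  if (nlevels(g) != 2) stop("status must have exactly 2 levels present", call. = FALSE)
  if (any(table(g) < 2)) stop("each status level needs n >= 2", call. = FALSE)
  # convention: statistic sign follows second level minus first (e.g.
  # amplified minus non-amplified when levels sort 0 < 1)
  tt <- welch_t(expr_gene[g == levels(g)[2]], expr_gene[g == levels(g)[1]],
                pooled = pooled)
  structure(list(
    gene = gene, grouping = grouping, test = "t_test",
    statistic = tt$statistic, p = tt$p, tier = significance_tier(tt$p),
    summaries = .level_summaries(expr_gene, g)
  ), class = "association_result")
}

#' Association of one gene's expression with an ordinal covariate
#'
#' Classical one-way ANOVA across the levels (unordered factor treatment;
#' the level order is preserved in the summaries for trend inspection).
#' With exactly two levels the F statistic equals the square of the pooled
#' t statistic.
#'
#' @param expr_gene numeric expression vector for one gene.
#' @param level ordinal covariate per sample (>= 2 levels, each n >= 2).
#' @inheritParams binary_association
#' @export
ordinal_association <- function(expr_gene, level, gene = NA_character_,
                                grouping = "stage") {
  g <- factor(level)
  if (nlevels(g) < 2) stop("need >= 2 levels", call. = FALSE)
  if (any(table(g) < 2)) stop("every level needs n >= 2", call. = FALSE)
  st <- .group_row_stats(matrix(expr_gene, nrow = 1), as.character(g))
  p <- .row_anova_p(st, length(expr_gene))
  ns <- vapply(st, `[[`, numeric(1), "n")
  k <- length(ns); N <- sum(ns)
  mus <- vapply(st, function(s) s$mean[1], numeric(1))
  vs <- vapply(st, function(s) s$var[1], numeric(1))
  grand <- sum(mus * ns) / N
  f <- (sum(ns * (mus - grand)^2) / (k - 1)) / (sum((ns - 1) * vs) / (N - k))
  structure(list(
    gene = gene, grouping = grouping, test = "anova",
    statistic = f, p = p, tier = significance_tier(p),
    summaries = .level_summaries(expr_gene, factor(level))
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s association (%s) for %s: statistic = %.4g, p = %.3g [%s]\n",
              x$grouping, x$test, x$gene, x$statistic, x$p, x$tier))
  print(x$summaries, digits = 4)
  invisible(x)
}
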