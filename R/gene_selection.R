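# Tumor-specificity filter: keep genes upregulated in one target tumor type
# versus EVERY other type, by linear fold change and per-comparison t-test.

#' Two-sample t test (Welch by default)
#'
#' Minimal two-sample test with explicit zero-variance conventions: if both
#' groups are constant and equal, p = 1; constant but unequal, p = 0 (the
#' limiting behavior of the t statistic).  The statistic carries the sign of
#' `mean(a) - mean(b)`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pooled use the classical pooled-variance Student statistic instead
#'   of the Welch unequal-variance form.
#' @return list with `statistic`, `df`, `p`.
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("degenerate input: each group needs >= 2 values", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(list(statistic = 0, df = na + nb - 2, p = 1))
    return(list(statistic = sign(ma - mb) * Inf, df = na + nb - 2, p = 0))
  }
  if (pooled) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se2 <- va / na + vb / nb
    se <- sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  stat <- (ma - mb) / se
  list(statistic = stat, df = df, p = 2 * stats::pt(-abs(stat), df))
}

#' Selection criteria for tumor-specific genes
#'
#' @param min_fold linear fold-change floor against every other tumor type
#'   (strict: fold must exceed `min_fold`); default 2.
#' @param max_p per-comparison raw p-value ceiling (strict); default 1e-5.
#'   No multiplicity correction is applied.
#' @param scale `"log2"` (folds computed as `2^(mean difference)`) or
#'   `"linear"` (ratio of means).
#' @param test `"welch"` or `"pooled"` two-sample t statistic.
#' @export
specificity_criteria <- function(min_fold = 2, max_p = 1e-5,
                                 scale = c("log2", "linear"),
                                 test = c("welch", "pooled")) {
  if (!is.finite(min_fold) || min_fold <= 1) abort_field("min_fold", "must be > 1")
  if (!is.finite(max_p) || max_p <= 0 || max_p >= 1) {
    abort_field("max_p", "must be in (0, 1)")
  }
  structure(list(min_fold = min_fold, max_p = max_p,
                 scale = match.arg(scale), test = match.arg(test)),
            class = "specificity_criteria")
}

# per-group rowwise means/vars for a genes x samples matrix
.group_row_stats <- function(expr, labels) {
  labels <- as.character(labels)
  lapply(stats::setNames(nm = unique(labels)), function(lv) {
    sub <- expr[, labels == lv, drop = FALSE]
    mu <- rowMeans(sub)
    v <- rowSums((sub - mu)^2) / (ncol(sub) - 1)
    list(n = ncol(sub), mean = mu, var = v)
  })
}

# vectorized Welch/pooled p over gene rows, with zero-variance conventions
.row_t_p <- function(sa, sb, pooled = FALSE) {
  na <- sa$n; nb <- sb$n
  d <- sa$mean - sb$mean
  if (pooled) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * sa$var + (nb - 1) * sb$var) / df
    se2 <- sp2 * (1 / na + 1 / nb)
  } else {
    se2 <- sa$var / na + sb$var / nb
    df <- se2^2 / ((sa$var / na)^2 / (na - 1) + (sb$var / nb)^2 / (nb - 1))
  }
  p <- 2 * stats::pt(-abs(d / sqrt(se2)), df)
  zero <- se2 == 0
  p[zero] <- ifelse(d[zero] == 0, 1, 0)
  p
}

# rowwise one-way ANOVA p across groups (classical F), with the same
# degenerate conventions as the t test
.row_anova_p <- function(stats_by_group, grand_n) {
  ns <- vapply(stats_by_group, `[[`, numeric(1), "n")
  k <- length(ns); N <- sum(ns)
  mu_mat <- vapply(stats_by_group, `[[`, stats_by_group[[1]]$mean, "mean")
  var_mat <- vapply(stats_by_group, `[[`, stats_by_group[[1]]$var, "var")
  grand <- as.vector(mu_mat %*% ns) / N
  ssb <- as.vector((mu_mat - grand)^2 %*% ns)
  ssw <- as.vector(var_mat %*% (ns - 1))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  p
}

#' Select genes specifically upregulated in one tumor type
#'
#' A gene is selected when, against EVERY other tumor type, its linear fold
#' change in the target type exceeds `criteria$min_fold` and the raw
#' two-sided t-test p-value is below `criteria$max_p`.  A one-way ANOVA p
#' across all types is reported per gene for transparency but is not part of
#' the selection predicate, and a Benjamini-Hochberg column over the
#' worst-case p is emitted without being used.
#'
#' @param expr genes x samples numeric matrix (log2 scale unless
#'   `criteria$scale == "linear"`), with gene symbols as rownames.
#' @param tumor_labels tumor type per sample (length `ncol(expr)`).
#' @param target_type the tumor type that must show the upregulation.
#' @param criteria a [specificity_criteria()].
#' @param gene_list optional character vector restricting the candidate
#'   genes (e.g. an immune-gene list); symbols are matched
#'   case-insensitively with a warning on case conflicts.
#' @return a `gene_panel` data.frame with columns gene, min_fold,
#'   max_p_across_comparisons, anova_p, p_bh, selected, ordered by
#'   descending minimum fold (ties by symbol).  Genes with missing values
#'   are excluded with a logged count (attribute `n_excluded_missing`).
#' @export
select_specific_genes <- function(expr, tumor_labels, target_type,
                                  criteria = specificity_criteria(),
                                  gene_list = NULL) {
  labels <- as.character(tumor_labels)
  if (length(labels) != ncol(expr)) {
    stop("tumor_labels must have one entry per sample column", call. = FALSE)
  }
  types <- unique(labels)
  if (length(types) < 2) stop("need >= 2 tumor types", call. = FALSE)
  if (!target_type %in% types) {
    stop("target type '", target_type, "' absent from tumor_labels", call. = FALSE)
  }
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
  if (!is.null(gene_list)) {
    hit <- tolower(rownames(expr)) %in% tolower(gene_list)
    exact <- rownames(expr) %in% gene_list
    if (any(hit & !exact)) {
      warning(sum(hit & !exact), " gene symbols matched case-insensitively")
    }
    expr <- expr[hit, , drop = FALSE]
  }
  missing <- rowSums(!is.finite(expr)) > 0
  n_excluded <- sum(missing)
  if (n_excluded > 0) {
    message("excluding ", n_excluded, " genes with missing values")
    expr <- expr[!missing, , drop = FALSE]
  }

  gs <- .group_row_stats(expr, labels)
  others <- setdiff(types, target_type)
  tgt <- gs[[target_type]]
  pooled <- criteria$test == "pooled"
  folds <- vapply(others, function(o) {
    if (criteria$scale == "log2") 2^(tgt$mean - gs[[o]]$mean)
    else tgt$mean / gs[[o]]$mean
  }, numeric(nrow(expr)))
  ps <- vapply(others, function(o) .row_t_p(tgt, gs[[o]], pooled = pooled),
               numeric(nrow(expr)))
  folds <- matrix(folds, nrow = nrow(expr))
  ps <- matrix(ps, nrow = nrow(expr))
  min_fold <- apply(folds, 1, min)
  max_p <- apply(ps, 1, max)
  anova_p <- .row_anova_p(gs, length(labels))
  selected <- min_fold > criteria$min_fold & max_p < criteria$max_p

  out <- data.frame(
    gene = rownames(expr), min_fold = min_fold,
    max_p_across_comparisons = max_p, anova_p = anova_p,
    p_bh = stats::p.adjust(max_p, "BH"), selected = selected,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$min_fold, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gene_panel", "data.frame"),
            target_type = target_type, criteria = criteria,
            n_excluded_missing = n_excluded)
}

#' Selected gene symbols of a panel, in panel order
#' @param panel a `gene_panel` (or a character vector, returned as-is).
#' @export
panel_genes <- function(panel) {
  if (is.character(panel)) return(panel)
  stopifnot(is.data.frame(panel))
  if ("selected" %in% names(panel)) panel$gene[panel$selected] else panel$gene
}
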