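# Subtype differential-expression panels and cross-cohort overlap
# statistics (Jaccard index and a combinatorial overlap null).

#' Differential-expression criteria for subtype panels
#'
#' @param min_fold linear fold floor, strict (default 1.5).
#' @param max_p raw two-sided p ceiling, strict (default 1e-3; use 1e-4 for
#'   genome-wide immune-gene scans).
#' @param scale `"log2"` or `"linear"` (see [specificity_criteria()]).
#' @param test `"welch"` or `"pooled"`.
#' @export
de_criteria <- function(min_fold = 1.5, max_p = 1e-3,
                        scale = c("log2", "linear"),
                        test = c("welch", "pooled")) {
  if (!is.finite(min_fold) || min_fold <= 1) abort_field("min_fold", "must be > 1")
  if (!is.finite(max_p) || max_p <= 0 || max_p >= 1) {
    abort_field("max_p", "must be in (0, 1)")
  }
  structure(list(min_fold = min_fold, max_p = max_p,
                 scale = match.arg(scale), test = match.arg(test)),
            class = "de_criteria")
}

#' Up/down gene panels between two subtypes
#'
#' Per-gene two-sample t test of UHR versus HR.  The up panel contains genes
#' whose UHR/HR linear fold exceeds `min_fold` with p below `max_p`; the
#' down panel is the mirror image.  The panels are disjoint by construction
#' and each is ordered by descending fold (ties by symbol).
#'
#' @param expr genes x samples matrix (log2 scale unless stated otherwise).
#' @param subtype_labels factor/character per sample; `uhr_level` names the
#'   level treated as UHR (default `"UHR"`).
#' @param criteria a [de_criteria()].
#' @param uhr_level label value identifying the UHR arm.
#' @return list with `up` and `down` data.frames (gene, log2fc, fold, p,
#'   direction) and `stats`, the full per-gene table.
#' @export
differential_genes <- function(expr, subtype_labels,
                               criteria = de_criteria(), uhr_level = "UHR") {
  labels <- as.character(subtype_labels)
  if (length(labels) != ncol(expr)) {
    stop("subtype_labels must have one entry per sample column", call. = FALSE)
  }
  lv <- unique(labels)
  if (length(lv) != 2 || !uhr_level %in% lv) {
    stop("need exactly two subtype labels including '", uhr_level, "'",
         call. = FALSE)
  }
  if (any(table(labels) < 2)) stop("each subtype needs >= 2 samples", call. = FALSE)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("g%04d", seq_len(nrow(expr)))
  gs <- .group_row_stats(expr, labels)
  other <- setdiff(lv, uhr_level)
  u <- gs[[uhr_level]]; h <- gs[[other]]
  log2fc <- if (criteria$scale == "log2") u$mean - h$mean else log2(u$mean / h$mean)
  p <- .row_t_p(u, h, pooled = criteria$test == "pooled")
  fold <- 2^log2fc
  stats_tab <- data.frame(
    gene = rownames(expr), log2fc = log2fc, fold = fold, p = p,
    p_bh = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE, row.names = NULL
  )
  up <- stats_tab[fold > criteria$min_fold & p < criteria$max_p, , drop = FALSE]
  down <- stats_tab[(1 / fold) > criteria$min_fold & p < criteria$max_p, , drop = FALSE]
  up <- up[order(-up$fold, up$gene), , drop = FALSE]
  down <- down[order(down$fold, down$gene), , drop = FALSE]  # largest HR/UHR fold first
  if (nrow(up)) up$direction <- "up"
  if (nrow(down)) down$direction <- "down"
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down, stats = stats_tab)
}

#' Overlap of two gene panels across cohorts
#'
#' Jaccard index `|A n B| / (|A| + |B| - |A n B|)` between two gene sets,
#' plus the combinatorial probability of the observed number of common
#' genes under the one-specific-subset null (see
#' [random_overlap_probability()]).
#'
#' @param panelA,panelB `gene_panel` objects, DE panel data.frames, or
#'   character vectors of symbols.
#' @return list of class `overlap_result`: `common` (sorted), `n1`, `n2`,
#'   `n_common`, `jaccard`, `random_prob`; `jaccard` is `NA` with a warning
#'   when both panels are empty.
#' @export
cross_cohort_overlap <- function(panelA, panelB) {
  a <- unique(panel_genes(panelA))
  b <- unique(panel_genes(panelB))
  common <- sort(intersect(a, b))
  uni <- length(a) + length(b) - length(common)
  jac <- if (uni == 0) {
    warning("both panels empty: Jaccard index undefined")
    NA_real_
  } else length(common) / uni
  rp <- if (length(a) && length(b)) {
    random_overlap_probability(length(a), length(b), length(common))
  } else NA_real_
  structure(list(common = common, n1 = length(a), n2 = length(b),
                 n_common = length(common), jaccard = jac, random_prob = rp),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of %d vs %d genes; Jaccard = %.3f; P(random) = %.3g\n",
              x$n_common, x$n1, x$n2, x$jaccard, x$random_prob))
  invisible(x)
}

#' Combinatorial probability of a specific p-gene overlap
#'
#' Probability `1 / (C(n1, p) * C(n2, p))` that two independently chosen
#' specific p-subsets coincide — a lower bound on the chance of observing
#' p common genes, not a hypergeometric tail.  Computed in log space.
#'
#' @param n1,n2 panel sizes.
#' @param p number of common genes (0 <= p <= min(n1, n2)).
#' @param hypergeom_tail also return the upper hypergeometric tail
#'   P(overlap >= p) for panels drawn from a universe of `universe` genes
#'   (optional, clearly separate from the headline value).
#' @param universe universe size for the optional tail.
#' @export
random_overlap_probability <- function(n1, n2, p, hypergeom_tail = FALSE,
                                       universe = NULL) {
  if (p < 0 || p > min(n1, n2)) {
    stop("p must satisfy 0 <= p <= min(n1, n2)", call. = FALSE)
  }
  out <- exp(-(lchoose(n1, p) + lchoose(n2, p)))
  if (hypergeom_tail) {
    if (is.null(universe) || universe < n1 + n2 - p) {
      stop("supply a universe size >= |A union B| for the tail", call. = FALSE)
    }
    tail <- stats::phyper(p - 1, n1, universe - n1, n2, lower.tail = FALSE)
    return(list(random_prob = out, hypergeom_tail = tail))
  }
  out
}
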