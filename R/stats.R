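# Nonparametric statistical battery: Kruskal-Wallis tests across protocol
# epochs, Bonferroni-corrected pairwise comparisons, and Spearman correlation
# matrices between metric families.

# tie-corrected Kruskal-Wallis H from pooled values and group sizes
.kw_statistic <- function(values, g) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(values)
  cc <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (cc == 0) return(NaN)
  h / cc
}

# all assignments of n items into groups of the given sizes (columns =
# membership vectors); used for the exact permutation null
.group_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  assign_rec <- function(avail, gi, acc) {
    if (gi > length(sizes)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    picks <- utils::combn(avail, sizes[gi], simplify = FALSE)
    for (p in picks) {
      acc2 <- acc
      acc2[p] <- gi
      assign_rec(setdiff(avail, p), gi + 1L, acc2)
    }
  }
  assign_rec(seq_len(n), 1L, integer(n))
  out
}

#' Kruskal-Wallis test
#'
#' Rank-based test for a common location across two or more groups, with tie
#' correction. By default the p-value comes from the chi-square approximation
#' (via [stats::kruskal.test()]); `exact = TRUE` enumerates the full
#' permutation null of group assignments, feasible for small totals
#' (<= ~12 observations), and reports `P(H >= H_obs)`.
#'
#' @param groups List of numeric vectors, one per group; >= 2 groups with
#'   >= 2 values each.
#' @param exact Use the exact permutation null instead of the chi-square
#'   approximation.
#' @return A list of class `test_report`: `comparison`, `statistic` (H),
#'   `p_value`, `method`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)), exact = TRUE) # p = 0.1
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  label <- paste(names(groups) %||% seq_along(groups), collapse = " vs ")
  if (length(unique(values)) == 1L) {
    # total ties: no evidence of any group effect
    return(.test_report(label, 0, 1, "Kruskal-Wallis (degenerate: all ties)"))
  }
  if (exact) {
    n <- length(values)
    if (n > 12L) stop("exact permutation null limited to <= 12 observations")
    h_obs <- .kw_statistic(values, g)
    hs <- vapply(.group_assignments(lengths(groups)),
                 function(a) .kw_statistic(values, a), numeric(1))
    p <- mean(hs >= h_obs - 1e-12)
    return(.test_report(label, h_obs, p, "Kruskal-Wallis (exact permutation)"))
  }
  kt <- kruskal.test(values, factor(g))
  .test_report(label, unname(kt$statistic), kt$p.value,
               "Kruskal-Wallis (chi-square approximation)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.test_report <- function(comparison, statistic, p_value, method,
                         alpha = NA_real_) {
  structure(
    list(comparison = comparison, statistic = statistic, p_value = p_value,
         alpha = alpha, significant = if (is.na(alpha)) NA else
           p_value <= alpha,
         method = method),
    class = "test_report"
  )
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic %.4g, p = %.4g%s [%s]\n",
              x$comparison, x$statistic, x$p_value,
              if (!is.na(x$alpha))
                sprintf(", alpha = %.4g (%s)", x$alpha,
                        if (isTRUE(x$significant)) "significant"
                        else "not significant")
              else "",
              x$method))
  invisible(x)
}

#' Bonferroni-corrected pairwise epoch comparisons
#'
#' For each metric and each named epoch pair, runs a two-group
#' Kruskal-Wallis test on the per-record epoch means, at the per-test level
#' `family_alpha / number of pairs`. With the default two stress-vs-no-stress
#' pairs and a family level of 0.05, the per-test threshold is 0.025.
#'
#' @param summaries Data frame of per-record epoch summaries with columns
#'   `metric`, `epoch`, `value` (one row per record, metric and epoch), as
#'   produced by [segment_by_epoch()] over records.
#' @param pairs List of length-2 character vectors of epoch labels; default
#'   compares each stress epoch with its preceding no-stress epoch.
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return Data frame with columns `metric`, `comparison`, `statistic`,
#'   `p_value`, `alpha`, `significant`. Pairs with a missing epoch are
#'   skipped with a warning.
#' @export
pairwise_epoch_tests <- function(summaries,
                                 pairs = list(c("rest", "arithmetic"),
                                              c("meditation1", "exercise")),
                                 family_alpha = 0.05) {
  stopifnot(all(c("metric", "epoch", "value") %in% names(summaries)))
  alpha <- family_alpha / length(pairs)
  rows <- list()
  for (metric in unique(summaries$metric)) {
    sm <- summaries[summaries$metric == metric, ]
    for (pair in pairs) {
      a <- sm$value[sm$epoch == pair[1L]]
      b <- sm$value[sm$epoch == pair[2L]]
      if (length(a) < 2L || length(b) < 2L) {
        warning("skipping pair ", pair[1L], " vs ", pair[2L], " for ",
                metric, ": epoch missing or too few records")
        next
      }
      kw <- kruskal_wallis(setNames(list(a, b), pair))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric,
        comparison = paste(pair, collapse = " vs "),
        statistic = kw$statistic, p_value = kw$p_value,
        alpha = alpha, significant = kw$p_value <= alpha
      )
    }
  }
  do.call(rbind, rows)
}

#' Spearman correlation matrix between two metric families
#'
#' Computes Spearman's rho and its p-value for every pairing of a column of
#' `a` with a column of `b`, on rows aligned across the two frames, with a
#' Bonferroni-corrected per-test level `family_alpha / (ncol(a) * ncol(b))`.
#' For the 4 ClassA metrics against the 8 traditional measures at a family
#' level of 0.05 this is 0.05 / 32, reported (to the printed precision) as
#' 0.0016.
#'
#' @param a,b Data frames of aligned metric columns (same row order; rows are
#'   the analysis units, e.g. per-record per-epoch means).
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return Data frame with columns `metric_a`, `metric_b`, `rho`, `p_value`,
#'   `alpha`, `significant`. Constant series give `NA` rho flagged
#'   non-significant.
#' @export
spearman_matrix <- function(a, b, family_alpha = 0.05) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  if (nrow(a) != nrow(b)) stop("`a` and `b` must be aligned on the same rows")
  alpha <- family_alpha / (ncol(a) * ncol(b))
  rows <- list()
  for (ca in names(a)) {
    for (cb in names(b)) {
      x <- a[[ca]]; y <- b[[cb]]
      if (sd(x) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric_a = ca, metric_b = cb, rho = NA_real_, p_value = NA_real_,
          alpha = alpha, significant = FALSE)
        next
      }
      ct <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        metric_a = ca, metric_b = cb,
        rho = unname(ct$estimate), p_value = ct$p.value,
        alpha = alpha, significant = ct$p.value <= alpha)
    }
  }
  do.call(rbind, rows)
}
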