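#' Nonparametric group comparison
#'
#' Runs the hypothesis test dictated by the study design, never falling
#' back silently between tests: a Wilcoxon signed-rank test for two
#' dependent groups (`"paired-2"`, e.g. eyes-open vs eyes-closed segments
#' from the same subjects, paired by index), a Mann-Whitney U test for two
#' independent groups (`"independent-2"`), and a Kruskal-Wallis test for
#' three or more independent groups (`"independent-k"`). P-values are
#' two-sided and exact where the underlying test provides exactness (small
#' samples without ties).
#'
#' @param values Named list of numeric vectors, one per group.
#' @param design `"paired-2"`, `"independent-2"` or `"independent-k"`.
#' @param alpha Significance level (default 0.01).
#' @return An object of class `group_test`: list with `test`, `statistic`,
#'   `p_value`, `group_sizes`, `alpha`, `significant`, and `degenerate`
#'   (TRUE when all paired differences are zero, in which case `p_value`
#'   is `NA`).
#' @export
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(4, 5, 6)), "independent-2")
compare_groups <- function(values,
                           design = c("paired-2", "independent-2",
                                      "independent-k"),
                           alpha = 0.01) {
  design <- match.arg(design)
  stopifnot(is.list(values), all(vapply(values, is.numeric, TRUE)))
  sizes <- lengths(values)
  res <- switch(design,
    "paired-2" = {
      if (length(values) != 2L) stop("paired-2 design requires 2 groups")
      if (sizes[1] != sizes[2]) {
        stop("paired design requires equal group lengths")
      }
      d <- values[[1]] - values[[2]]
      if (all(d == 0)) {
        return(structure(list(test = "wilcoxon-signed-rank", statistic = NA_real_,
                              p_value = NA_real_, group_sizes = sizes,
                              alpha = alpha, significant = FALSE,
                              degenerate = TRUE),
                         class = "group_test"))
      }
      w <- stats::wilcox.test(values[[1]], values[[2]], paired = TRUE)
      list(test = "wilcoxon-signed-rank", statistic = unname(w$statistic),
           p_value = w$p.value)
    },
    "independent-2" = {
      if (length(values) != 2L) stop("independent-2 design requires 2 groups")
      w <- stats::wilcox.test(values[[1]], values[[2]])
      list(test = "mann-whitney-u", statistic = unname(w$statistic),
           p_value = w$p.value)
    },
    "independent-k" = {
      if (length(values) < 2L) stop("independent-k design requires >= 2 groups")
      k <- stats::kruskal.test(values)
      list(test = "kruskal-wallis", statistic = unname(k$statistic),
           p_value = k$p.value)
    }
  )
  structure(c(res, list(group_sizes = sizes, alpha = alpha,
                        significant = is.finite(res$p_value) &&
                          res$p_value < alpha,
                        degenerate = FALSE)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: statistic = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$test, x$statistic, x$p_value,
              if (isTRUE(x$significant)) "" else "not ", x$alpha))
  invisible(x)
}

#' Pairwise post-hoc Mann-Whitney tests
#'
#' One Mann-Whitney U test per unordered pair of groups, reported with raw
#' (uncorrected) p-values by default; an optional Holm correction is
#' available.
#'
#' @param values Named list of numeric vectors (>= 2 groups).
#' @param alpha Significance level. @param correct Apply a Holm correction
#'   across the pairs?
#' @return Named list of `group_test` objects, names `"g1 vs g2"`.
#' @export
pairwise_posthoc <- function(values, alpha = 0.01, correct = FALSE) {
  stopifnot(length(values) >= 2L)
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  pairs <- utils::combn(names(values), 2, simplify = FALSE)
  out <- lapply(pairs, function(p) {
    compare_groups(values[p], "independent-2", alpha = alpha)
  })
  names(out) <- vapply(pairs, paste, "", collapse = " vs ")
  if (correct) {
    padj <- stats::p.adjust(vapply(out, `[[`, 0, "p_value"), "holm")
    for (i in seq_along(out)) {
      out[[i]]$p_value <- unname(padj[i])
      out[[i]]$significant <- padj[i] < alpha
    }
  }
  out
}
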