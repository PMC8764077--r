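#' Stratified descriptive table with nonparametric tests
#'
#' One row block per variable, one column per stratum of `group`.
#' Continuous variables show median (q25, q75) and are compared by the
#' Wilcoxon rank-sum test (2 strata) or Kruskal-Wallis (>2). Categorical
#' variables show count (%) per level and are compared by Pearson's
#' chi-squared, switching to Fisher's exact test whenever any expected cell
#' count is below 10.
#'
#' @param data Data frame (typically a validated `survey_dataset`).
#' @param group Name of the stratifying categorical column.
#' @param variables Character vector of columns to summarise; defaults to
#'   every column except `group` and identifiers.
#' @param expected_cutoff Expected-count threshold for the Fisher switch.
#' @return A data frame: `variable`, `level`, one summary column per
#'   stratum, `test`, `p_value` (on the first row of each block).
#' @export
table_one <- function(data, group, variables = NULL, expected_cutoff = 10) {
  data <- as.data.frame(data)
  g <- data[[group]]
  if (is.null(g)) stop("grouping column '", group, "' not found", call. = FALSE)
  g <- droplevels(factor(g))
  if (nlevels(g) < 2L) stop("grouping variable needs >= 2 observed levels",
                            call. = FALSE)
  if (is.null(variables)) {
    variables <- setdiff(names(data), c(group, "respondent_id"))
  }
  strata <- levels(g)
  blocks <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 6L) {
      cell <- vapply(strata, function(s) {
        q <- stats::quantile(x[g == s], c(0.5, 0.25, 0.75), names = FALSE)
        sprintf("%g (%g, %g)", signif(q[1], 3), signif(q[2], 3), signif(q[3], 3))
      }, character(1))
      tst <- if (nlevels(g) == 2L) {
        list(name = "Wilcoxon rank-sum",
             p = stats::wilcox.test(x ~ g, exact = FALSE, correct = FALSE)$p.value)
      } else {
        list(name = "Kruskal-Wallis", p = stats::kruskal.test(x, g)$p.value)
      }
      out <- data.frame(variable = v, level = "median (IQR)",
                        t(cell), test = tst$name, p_value = tst$p,
                        check.names = FALSE)
      names(out)[3:(2 + length(strata))] <- strata
      out
    } else {
      x <- droplevels(factor(x))
      tab <- table(x, g)
      tst <- categorical_test(tab, expected_cutoff)
      cell <- matrix(sprintf("%d (%.0f%%)", tab,
                             100 * prop.table(tab, margin = 2L)),
                     nrow = nrow(tab), dimnames = dimnames(tab))
      out <- data.frame(variable = v, level = rownames(tab),
                        cell, test = c(tst$name, rep("", nrow(tab) - 1L)),
                        p_value = c(tst$p, rep(NA_real_, nrow(tab) - 1L)),
                        check.names = FALSE)
      names(out)[3:(2 + length(strata))] <- strata
      out
    }
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

# chi-squared / Fisher switching rule: Fisher's exact test whenever any
# expected cell frequency is below the cutoff (default 10)
categorical_test <- function(tab, expected_cutoff = 10) {
  if (any(dim(tab) < 2L) || any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("degenerate stratum: test skipped")
    return(list(name = "(skipped)", p = NA_real_))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < expected_cutoff)) {
    p <- tryCatch(stats::fisher.test(tab)$p.value,
                  error = function(e)
                    stats::fisher.test(tab, simulate.p.value = TRUE,
                                       B = 1e4)$p.value)
    list(name = "Fisher's exact", p = p)
  } else {
    list(name = "Pearson's chi-squared",
         p = stats::chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Does the chi-squared/Fisher rule select Fisher's exact test?
#'
#' Pure function of the expected-count table: `TRUE` when any expected cell
#' frequency under independence is below the cutoff.
#'
#' @param tab A contingency table (matrix).
#' @param expected_cutoff Threshold (default 10).
#' @return Logical.
#' @export
use_fisher <- function(tab, expected_cutoff = 10) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  any(expected < expected_cutoff)
}

#' Pairwise Spearman correlation matrix with rho-test p-values
#'
#' Midrank handling of ties; constant variables give `NA` with a warning
#' flag.
#'
#' @param data Data frame.
#' @param variables Character vector of numeric columns.
#' @return List with `rho` (symmetric, unit diagonal) and `p` matrices.
#' @export
spearman_matrix <- function(data, variables) {
  data <- as.data.frame(data)
  k <- length(variables)
  rho <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(variables, variables)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- data[[variables[i]]]
      y <- data[[variables[j]]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ",
                             variables[i], " vs ", variables[j], call. = FALSE)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("constant variable: correlation undefined for ",
                variables[i], " vs ", variables[j])
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Wilcoxon signed-rank test of paired scores
#'
#' Within-respondent comparison of the two intention scores (each
#' respondent rated both measures). Zero differences are dropped per the
#' standard signed-rank convention; the continuity correction is off by
#' default.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param correct Continuity correction for the normal approximation.
#' @param exact Exact p-value; `NULL` (default) lets `wilcox.test` decide.
#' @return List with `statistic`, `p_value`, `n_nonzero`, `median_x`,
#'   `median_y`.
#' @export
paired_wilcoxon <- function(x, y, correct = FALSE, exact = NULL) {
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero: degenerate test")
    return(list(statistic = 0, p_value = 1, n_nonzero = 0L,
                median_x = stats::median(x), median_y = stats::median(y)))
  }
  wt <- stats::wilcox.test(x, y, paired = TRUE, correct = correct,
                           exact = exact)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = sum(d != 0),
       median_x = stats::median(x), median_y = stats::median(y))
}
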