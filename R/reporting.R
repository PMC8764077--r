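#' Coefficient table of the bivariate model (three-block layout)
#'
#' Arranges the posterior summary into one row per covariate term with
#' estimate and 95% CrI columns for the COVID-19 vaccine location, the
#' contact-tracing-app location, and the rhogit-linked correlation; rows
#' whose CrI excludes zero carry an asterisk flag (the "bold" convention).
#' Reference categories never appear as rows; they are listed in the
#' `footnote` attribute.
#'
#' @param summary Output of [summarize_bbg()].
#' @param codings Optional named list of `categorical_coding` objects whose
#'   printed intervals annotate matching category rows.
#' @param references Optional character vector of reference-category
#'   descriptions for the footnote.
#' @return Data frame (class `bbg_table`) with a `footnote` attribute.
#' @export
render_table2 <- function(summary, codings = NULL, references = NULL) {
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  one_block <- function(b) {
    s <- summary[summary$block == b, , drop = FALSE]
    s$label <- sub("^[^:]+:", "", s$term)
    s
  }
  b1 <- one_block("mu1"); b2 <- one_block("mu2"); b3 <- one_block("rho")
  labels <- unique(c(b1$label, b2$label, b3$label))
  cell <- function(s, lab) {
    i <- match(lab, s$label)
    if (is.na(i)) return(c("", "", ""))
    c(paste0(fmt(s$mean[i]), if (s$excludes_zero[i]) "*" else ""),
      paste0("(", fmt(s$q2.5[i]), ", ", fmt(s$q97.5[i]), ")"),
      "")
  }
  rows <- lapply(labels, function(lab) {
    interval <- ""
    if (!is.null(codings)) {
      for (cd in codings) {
        ints <- coding_intervals(cd)
        hit <- names(ints)[vapply(names(ints), function(l)
          grepl(l, lab, fixed = TRUE), logical(1))]
        if (length(hit)) interval <- ints[[hit[1]]]
      }
    }
    data.frame(term = lab, interval = interval,
               vaccine = cell(b1, lab)[1], vaccine_cri = cell(b1, lab)[2],
               cta = cell(b2, lab)[1], cta_cri = cell(b2, lab)[2],
               rhogit = cell(b3, lab)[1], rhogit_cri = cell(b3, lab)[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "footnote") <- c(
    "* 95% CrI outside the null effect.",
    if (!is.null(references))
      paste("Reference category:", paste(references, collapse = ", ")))
  class(out) <- c("bbg_table", "data.frame")
  out
}

#' Odds-ratio table layout for the cumulative logistic fits
#'
#' One row per term with `OR`, `95% CI` and p-value columns; reference rows
#' print as `1.00` with dashes; thresholds keep their `Intercept k|k+1`
#' labels.
#'
#' @param or_table Output of [odds_ratios()].
#' @return Data frame with character columns `term`, `OR`, `CI95`, `p`.
#' @export
render_table3 <- function(or_table) {
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  fmt_p <- function(p) ifelse(is.na(p), "-",
                              ifelse(p < 0.001, "< 0.001",
                                     formatC(p, format = "f", digits = 3)))
  data.frame(
    term = or_table$term,
    OR = fmt(or_table$or),
    CI95 = ifelse(or_table$reference, "-",
                  paste0("(", fmt(or_table$ci_low), "-",
                         fmt(or_table$ci_high), ")")),
    p = ifelse(or_table$reference, "-", fmt_p(or_table$p_value)),
    stringsAsFactors = FALSE)
}
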