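#' Survey schema: canonical fields, column bindings, and ranges
#'
#' Describes the respondent-level table the pipeline consumes: two 0-100
#' intention scores, four 0-4 motivation items, three 0-100 perceived-risk
#' items, three 0-100 trust items, further 0-100 scores, a 1-7 conspiracy
#' scale and demographics. `columns` rebinds canonical field names to the
#' headers actually present in a file, so external deposits can be read
#' without code changes.
#'
#' @param columns Named character vector mapping canonical field names to
#'   file column names. Defaults to the identity mapping.
#' @param recode_motivation If `TRUE` (default) motivation items collected on
#'   0-4 are recoded to the 1-4 modelling scale by collapsing the bottom two
#'   raw levels (0 and 1) into level 1.
#' @return A list with elements `fields` (per-field metadata), `columns`, and
#'   `recode_motivation`, of class `"survey_schema"`.
#' @export
survey_schema <- function(columns = NULL, recode_motivation = TRUE) {
  num <- function(lo, hi) list(type = "numeric", range = c(lo, hi))
  fields <- list(
    respondent_id       = list(type = "id"),
    vaccine_intent      = num(0, 100),
    cta_intent          = num(0, 100),
    motivation_vaccine_self   = num(0, 4),
    motivation_vaccine_others = num(0, 4),
    motivation_cta_self       = num(0, 4),
    motivation_cta_others     = num(0, 4),
    risk_likelihood     = num(0, 100),
    risk_severity       = num(0, 100),
    risk_scare          = num(0, 100),
    trust_international = num(0, 100),
    trust_national      = num(0, 100),
    trust_scientific    = num(0, 100),
    trust_local         = num(0, 100),
    self_efficacy       = num(0, 100),
    vaccine_doubts      = num(0, 100),
    flu_vaccine_2019    = list(type = "binary"),
    conspiracy          = num(1, 7),
    gender              = list(type = "factor",
                               levels = c("female", "male")),
    age                 = num(.Machine$double.eps, 120),
    education           = list(type = "factor",
                               levels = c("middle school", "high school",
                                          "university degree or higher")),
    family_status       = list(type = "factor", levels = NULL),
    job                 = list(type = "factor",
                               levels = c("employee", "business-owner",
                                          "retired-unemployed", "student")),
    salary              = list(type = "factor", levels = NULL),
    covid_contact       = list(type = "binary")
  )
  cols <- stats::setNames(names(fields), names(fields))
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), names(fields))
    if (length(bad)) {
      stop("unknown schema fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cols[names(columns)] <- columns
  }
  structure(list(fields = fields, columns = cols,
                 recode_motivation = recode_motivation),
            class = "survey_schema")
}

#' Read and validate a respondent-level survey table
#'
#' Reads a delimited text file (comma or tab, auto-detected, header row),
#' binds columns through the schema, drops rows incomplete on any modelled
#' field (complete-case analysis; no imputation), and validates ranges and
#' identifier uniqueness. The count of dropped rows is attached as the
#' `drop_report` attribute.
#'
#' @param path Path to a delimited text file.
#' @param schema A [survey_schema()].
#' @return A validated `survey_dataset` data frame.
#' @export
read_survey <- function(path, schema = survey_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(schema$columns), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- raw[unname(schema$columns)]
  names(dat) <- names(schema$columns)
  validate_survey(dat, schema)
}

#' Validate (and recode) a survey data frame
#'
#' Idempotent: validating an already-validated dataset returns it unchanged.
#'
#' @param data Data frame with the canonical survey columns.
#' @param schema A [survey_schema()].
#' @return A `survey_dataset` with a `drop_report` attribute.
#' @export
validate_survey <- function(data, schema = survey_schema()) {
  need <- names(schema$fields)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[need]

  complete <- stats::complete.cases(data)
  dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (nrow(data) == 0L) stop("no complete rows after filtering", call. = FALSE)

  if (anyDuplicated(data$respondent_id)) {
    stop("respondent_id values are not unique", call. = FALSE)
  }

  for (fld in need) {
    meta <- schema$fields[[fld]]
    x <- data[[fld]]
    if (meta$type == "numeric") {
      if (!is.numeric(x)) {
        stop("field '", fld, "' must be numeric", call. = FALSE)
      }
      rng <- meta$range
      # motivation items are accepted on the raw 0-4 collection scale;
      # the recode below moves them onto 1-4
      bad <- which(x < rng[1] | x > rng[2])
      if (length(bad)) {
        stop("value out of range [", rng[1], ", ", rng[2], "] in field '",
             fld, "' for respondent_id = ",
             data$respondent_id[bad[1]], call. = FALSE)
      }
    } else if (meta$type == "binary") {
      if (is.logical(x)) x <- as.integer(x)
      if (is.character(x)) x <- as.integer(tolower(x) %in% c("yes", "1", "true"))
      if (!all(x %in% c(0, 1))) {
        stop("field '", fld, "' must be binary (0/1)", call. = FALSE)
      }
      data[[fld]] <- as.integer(x)
    } else if (meta$type == "factor") {
      x <- as.character(x)
      if (!is.null(meta$levels)) {
        bad <- setdiff(unique(x), meta$levels)
        if (length(bad)) {
          stop("unknown level(s) in field '", fld, "': ",
               paste(bad, collapse = ", "), call. = FALSE)
        }
        data[[fld]] <- factor(x, levels = meta$levels)
      } else {
        data[[fld]] <- factor(x)
      }
    }
  }

  if (isTRUE(schema$recode_motivation)) {
    mot <- c("motivation_vaccine_self", "motivation_vaccine_others",
             "motivation_cta_self", "motivation_cta_others")
    for (m in mot) data[[m]] <- pmax(1L, as.integer(data[[m]]))
  }

  rownames(data) <- NULL
  structure(data,
            drop_report = list(incomplete = dropped),
            class = c("survey_dataset", "data.frame"))
}

#' Write a rectangular report table
#'
#' Delimited output round-trips losslessly through [read_report_table()];
#' markdown output is a GitHub-style pipe table.
#'
#' @param table A data frame (may have zero rows).
#' @param path Output file path.
#' @param format `"tsv"`, `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, format = c("tsv", "csv", "markdown")) {
  format <- match.arg(format)
  table <- as.data.frame(table)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "markdown") {
    fmt_cell <- function(x) {
      if (is.numeric(x)) formatC(x, format = "g", digits = 6) else as.character(x)
    }
    body <- vapply(seq_len(ncol(table)),
                   function(j) fmt_cell(table[[j]]), character(nrow(table)))
    if (nrow(table) == 1L) body <- matrix(body, nrow = 1L)
    header <- paste0("| ", paste(names(table), collapse = " | "), " |")
    rule <- paste0("|", paste(rep("---", ncol(table)), collapse = "|"), "|")
    rows <- if (nrow(table)) {
      apply(body, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    } else character()
    writeLines(c(header, rule, rows), path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    utils::write.table(table, path, sep = sep, row.names = FALSE,
                       quote = TRUE, na = "NA", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read back a delimited report table written by [write_table()]
#' @param path File path.
#' @param format `"tsv"` or `"csv"`.
#' @return A data frame.
#' @export
read_report_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}
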