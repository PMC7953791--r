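#' Read labelled validation cases from a delimited file
#'
#' Two dialects are accepted. Wide: columns `case_id`, `true_disease_id`,
#' `category`, `organ` followed by one column per antibody whose cells are
#' result tokens (`+`, `-`, `pos`, `neg`, ...) or blank (marker not tested).
#' Long: columns `case_id`, `true_disease_id`, `category`, `organ`,
#' `antibody`, `result`, one row per marker result. The dialect is detected
#' from the presence of an `antibody` column.
#'
#' @param path CSV (`.csv`) or TSV file path.
#' @param registry Optional [antibody_registry()] for name resolution.
#' @return List of [validation_case()] objects.
#' @export
read_cases <- function(path, registry = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("case file not found: %s", path), "ihcdiff_io_error")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  meta <- c("case_id", "true_disease_id", "category", "organ")
  if (!all(meta %in% names(tab))) {
    abort(sprintf("case file %s lacks column(s): %s", path,
                  paste(setdiff(meta, names(tab)), collapse = ", ")),
          "ihcdiff_load_error")
  }
  long <- "antibody" %in% names(tab)
  build <- function(id, nms, toks, category, organ, true_id, row_hint) {
    panel <- tryCatch(
      case_panel(stats::setNames(toks, nms), registry = registry),
      ihcdiff_error = function(e) {
        abort(sprintf("case '%s' (near row %d): %s", id, row_hint,
                      conditionMessage(e)),
              "ihcdiff_load_error")
      })
    validation_case(id, panel, true_id, category, organ)
  }
  if (long) {
    if (!"result" %in% names(tab)) {
      abort(sprintf("long-format case file %s needs a `result` column", path),
            "ihcdiff_load_error")
    }
    ids <- unique(tab$case_id)
    lapply(ids, function(id) {
      rows <- which(tab$case_id == id)
      build(id, tab$antibody[rows], tab$result[rows],
            tab$category[rows[1]], tab$organ[rows[1]],
            tab$true_disease_id[rows[1]], rows[1] + 1L)
    })
  } else {
    ab_cols <- setdiff(names(tab), meta)
    lapply(seq_len(nrow(tab)), function(i) {
      toks <- vapply(ab_cols, function(a) tab[[a]][i], character(1))
      keep <- !is.na(toks) & nzchar(trimws(toks))
      build(tab$case_id[i], ab_cols[keep], toks[keep],
            tab$category[i], tab$organ[i], tab$true_disease_id[i], i + 1L)
    })
  }
}

#' Write validation cases to a long-format TSV
#' @param cases List of [validation_case()].
#' @param destination Output path.
#' @export
write_cases <- function(cases, destination) {
  rows <- lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id, true_disease_id = cs$true_disease_id,
               category = cs$category, organ = cs$organ,
               antibody = names(cs$panel),
               result = ifelse(as.vector(cs$panel), "+", "-"),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), destination, sep = "\t",
                     quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(destination)
}
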