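#' Construct a labelled validation case
#'
#' @param case_id Case identifier.
#' @param panel A [case_panel()] (or named vector accepted by it).
#' @param true_disease_id Ground-truth diagnosis (a KB disease id).
#' @param category Disease category label (see [disease_categories()]).
#' @param organ Organ label.
#' @return List of class `validation_case`.
#' @export
validation_case <- function(case_id, panel, true_disease_id,
                            category = NA_character_, organ = NA_character_) {
  if (!inherits(panel, "case_panel")) panel <- case_panel(panel)
  structure(list(case_id = as.character(case_id), panel = panel,
                 true_disease_id = as.character(true_disease_id),
                 category = as.character(category),
                 organ = as.character(organ)),
            class = "validation_case")
}

#' Filter validation cases the way the validation protocol prescribes
#'
#' Per case: (1) prognostic-only markers (e.g. EGFR, p53 — informative about
#' outcome, not tumour origin) are stripped from the panel; (2) cases whose
#' panel then holds no diagnostic marker are excluded with reason
#' `"no-diagnostic-markers"`; (3) cases with fewer than `min_markers`
#' remaining are excluded with reason `"fewer-than-3-antibodies"`. Panels
#' with unresolvable antibody names are excluded with reason
#' `"unknown-antibody"` rather than stopping the run.
#'
#' @param cases List of [validation_case()] objects.
#' @param registry An [antibody_registry()] flagging `prognostic_only`
#'   markers.
#' @param min_markers Minimum number of diagnostic markers to retain a case
#'   (default 3).
#' @return List with `retained` (cases with stripped panels) and `excluded`
#'   (data frame of `case_id`, `reason`).
#' @export
filter_cases <- function(cases, registry, min_markers = 3L) {
  retained <- list()
  excl <- list()
  drop <- function(id, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(case_id = id, reason = reason,
                                             stringsAsFactors = FALSE)
  }
  prog <- registry$canonical_name[registry$prognostic_only]
  for (cs in cases) {
    canon <- tryCatch(resolve_antibody(names(cs$panel), registry),
                      ihcdiff_unknown_antibody_error = function(e) NULL)
    if (is.null(canon)) {
      drop(cs$case_id, "unknown-antibody")
      next
    }
    keep <- !(canon %in% prog)
    if (!any(keep)) {
      drop(cs$case_id, "no-diagnostic-markers")
      next
    }
    if (sum(keep) < min_markers) {
      drop(cs$case_id, sprintf("fewer-than-%d-antibodies", min_markers))
      next
    }
    cs$panel <- structure(stats::setNames(as.vector(cs$panel)[keep], canon[keep]),
                          class = "case_panel")
    retained[[length(retained) + 1L]] <- cs
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(case_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(retained = retained, excluded = excluded)
}

#' Was the true diagnosis hit within the top-k differential?
#'
#' A hit requires the true disease — or any disease sharing its equivalence
#' group (entries differing only by anatomical site, e.g. gastrointestinal
#' stromal tumour of the stomach vs small intestine) — to appear among the
#' first `k` ranked diagnoses.
#'
#' @param true_disease_id Ground-truth disease id.
#' @param ranked Output of [rank_diagnoses()].
#' @param kb The knowledge base the ranking used.
#' @param k Window size (default 10).
#' @return Logical scalar.
#' @export
is_hit <- function(true_disease_id, ranked, kb, k = 10L) {
  i <- match(true_disease_id, kb$diseases$disease_id)
  if (is.na(i)) {
    abort(sprintf("unknown true disease id '%s'", true_disease_id),
          "ihcdiff_reference_error")
  }
  grp <- kb$diseases$equivalence_group[i]
  accept <- true_disease_id
  if (!is.na(grp) && nzchar(grp)) {
    accept <- kb$diseases$disease_id[
      !is.na(kb$diseases$equivalence_group) &
        kb$diseases$equivalence_group == grp]
  }
  top <- utils::head(ranked$disease_id, k)
  any(top %in% accept)
}

#' Evaluate a labelled case set: top-k hit rates per category
#'
#' Runs [rank_diagnoses()] on every case, determines hits with [is_hit()]
#' at `k = config$top_k`, and tallies accurate/error counts per disease
#' category and overall. Rates are percentages of exact counts.
#'
#' @param cases List of [validation_case()] (already passed through
#'   [filter_cases()]).
#' @param kb An [ihc_kb()].
#' @param config A [ranker_config()].
#' @param excluded Optional exclusion data frame from [filter_cases()],
#'   carried into the report.
#' @return A `hit_rate_report`: list with `per_category` (data frame
#'   `category`, `n_cases`, `n_accurate`, `n_error`, `error_rate`),
#'   `totals` (`n_cases`, `n_accurate`, `n_error`, `hit_rate`, `error_rate`)
#'   and `excluded`.
#' @export
evaluate_dataset <- function(cases, kb, config = ranker_config(),
                             excluded = NULL) {
  if (length(cases) == 0L) {
    abort("no cases to evaluate", "ihcdiff_argument_error")
  }
  cat_lab <- vapply(cases, function(cs) cs$category, character(1))
  hits <- vapply(cases, function(cs) {
    ranked <- suppressMessages(rank_diagnoses(kb, cs$panel, config))
    is_hit(cs$true_disease_id, ranked, kb, k = config$top_k)
  }, logical(1))
  tab <- data.frame(category = cat_lab, hit = hits, stringsAsFactors = FALSE)
  agg_n <- tapply(tab$hit, tab$category, length)
  agg_h <- tapply(tab$hit, tab$category, sum)
  cats <- intersect(disease_categories(), names(agg_n))
  cats <- c(cats, setdiff(names(agg_n), cats))  # stable category order
  per_category_counts <- stats::setNames(
    lapply(cats, function(cg) c(n_cases = agg_n[[cg]],
                                n_accurate = agg_h[[cg]])), cats)
  hit_rate_report(per_category_counts, excluded = excluded)
}

#' Assemble a hit-rate report from accurate/total counts
#'
#' The report arithmetic (error and hit rates, totals) is recomputed from
#' the integer counts, so a report can also be built directly from published
#' per-category tallies.
#'
#' @param per_category Named list (names = category labels), each element a
#'   vector with `n_cases` and `n_accurate`.
#' @param excluded Optional data frame of `case_id`, `reason`.
#' @return A `hit_rate_report`.
#' @export
hit_rate_report <- function(per_category, excluded = NULL) {
  n_cases <- vapply(per_category, function(x) as.numeric(x[["n_cases"]]),
                    numeric(1))
  n_acc <- vapply(per_category, function(x) as.numeric(x[["n_accurate"]]),
                  numeric(1))
  if (any(n_acc > n_cases) || any(n_cases < 0)) {
    abort("n_accurate may not exceed n_cases", "ihcdiff_argument_error")
  }
  per <- data.frame(category = names(per_category),
                    n_cases = n_cases,
                    n_accurate = n_acc,
                    n_error = n_cases - n_acc,
                    error_rate = ifelse(n_cases > 0,
                                        100 * (n_cases - n_acc) / n_cases, NA),
                    stringsAsFactors = FALSE, row.names = NULL)
  tot_n <- sum(per$n_cases)
  tot_a <- sum(per$n_accurate)
  if (is.null(excluded)) {
    excluded <- data.frame(case_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(
    per_category = per,
    totals = list(n_cases = tot_n, n_accurate = tot_a,
                  n_error = tot_n - tot_a,
                  hit_rate = 100 * tot_a / tot_n,
                  error_rate = 100 * (tot_n - tot_a) / tot_n),
    excluded = excluded),
    class = "hit_rate_report")
}

#' @export
print.hit_rate_report <- function(x, ...) {
  cat(format_hit_rate_report(x), sep = "\n")
  invisible(x)
}

#' Render a hit-rate report as a category-by-category table
#'
#' Mirrors the conventional published layout: one row per category with
#' accurate/error counts and the error rate to one decimal place, then a
#' totals row with the overall hit rate.
#'
#' @param report A `hit_rate_report`.
#' @return Character vector of tab-separated lines.
#' @export
format_hit_rate_report <- function(report) {
  per <- report$per_category
  lines <- c("category\tn_cases\tn_accurate\tn_error\terror_rate_pct",
             sprintf("%s\t%d\t%d\t%d\t%.1f", per$category, per$n_cases,
                     per$n_accurate, per$n_error, per$error_rate),
             sprintf("TOTAL\t%d\t%d\t%d\t%.1f  (hit rate %.1f%%)",
                     report$totals$n_cases, report$totals$n_accurate,
                     report$totals$n_error, report$totals$error_rate,
                     report$totals$hit_rate))
  if (nrow(report$excluded)) {
    lines <- c(lines, sprintf("# excluded: %d case(s)", nrow(report$excluded)))
  }
  lines
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' The uncorrected Pearson statistic `sum (O - E)^2 / E` on 1 degree of
#' freedom (no Yates continuity correction), with the p-value from the
#' chi-square survival function.
#'
#' @param table 2x2 numeric matrix of counts.
#' @return List of class `chi_square_result` with `statistic`,
#'   `degrees_of_freedom`, `p_value`.
#' @examples
#' pearson_chi_square(matrix(c(441, 298, 121, 84), 2))$p_value  # 0.866
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || anyNA(table)) {
    abort("`table` must be a 2x2 matrix of non-negative counts",
          "ihcdiff_argument_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("degenerate table: a margin is zero", "ihcdiff_degenerate_table_error")
  }
  ht <- stats::chisq.test(table, correct = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 degrees_of_freedom = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Compare the error rates of two hit-rate reports
#'
#' Builds the accurate/error-by-dataset 2x2 table from the two reports'
#' totals and applies [pearson_chi_square()].
#'
#' @param report_a,report_b `hit_rate_report` objects.
#' @return A `chi_square_result`.
#' @export
compare_error_rates <- function(report_a, report_b) {
  tab <- rbind(c(report_a$totals$n_accurate, report_a$totals$n_error),
               c(report_b$totals$n_accurate, report_b$totals$n_error))
  pearson_chi_square(tab)
}

#' Deterministically split a case set into two partitions
#'
#' Shuffles the cases under the seed, then cuts at
#' `round(n * ratio[1])`. The partitions are disjoint and cover the input.
#'
#' @param cases List of cases (any list).
#' @param ratio Length-2 positive numeric summing to 1 (default `c(0.6, 0.4)`,
#'   the conventional training:validation split).
#' @param seed Integer seed; the split is reproducible and does not disturb
#'   the caller's RNG state.
#' @return List with elements `a` and `b`.
#' @export
split_dataset <- function(cases, ratio = c(0.6, 0.4), seed = 1L) {
  if (length(cases) == 0L) {
    abort("no cases to split", "ihcdiff_argument_error")
  }
  if (length(ratio) != 2L || any(ratio < 0) || abs(sum(ratio) - 1) > 1e-9) {
    abort("`ratio` must be two non-negative numbers summing to 1",
          "ihcdiff_argument_error")
  }
  n <- length(cases)
  perm <- with_local_seed(seed, sample.int(n))
  n_a <- round(n * ratio[1])
  list(a = cases[perm[seq_len(n_a)]],
       b = cases[perm[setdiff(seq_len(n), seq_len(n_a))]])
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
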