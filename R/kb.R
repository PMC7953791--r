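#' Encode a textbook positivity term as a probability fraction
#'
#' Curated IHC references often state marker positivity qualitatively rather
#' than numerically. This encoder maps the six-term curation vocabulary onto
#' fixed probability fractions: "always" = 0.95, "often" = 0.75,
#' "in about a half of cases" (or "half") = 0.50, "seldom" = 0.30,
#' "rarely"/"occasionally" = 0.10 and "never" = 0. Numeric text such as
#' `"49%"` or `"49"` is interpreted as a percentage and divided by 100.
#'
#' @param term Character scalar: a vocabulary term (case-insensitive) or a
#'   numeric percentage with or without a trailing `%`.
#' @return A probability fraction in `[0, 1]`.
#' @examples
#' encode_positivity_term("often")   # 0.75
#' encode_positivity_term("never")   # 0
#' encode_positivity_term("49%")     # 0.49
#' @export
encode_positivity_term <- function(term) {
  if (!is.character(term) || length(term) != 1L || is.na(term)) {
    abort("`term` must be a single character string", "ihcdiff_argument_error")
  }
  key <- tolower(trimws(term))
  key <- gsub("\\s+", " ", key)
  hit <- .positivity_vocabulary[[key]]
  if (!is.null(hit)) return(hit)
  # numeric percentage, with or without "%"
  num <- sub("%$", "", key)
  if (grepl("^[0-9]*\\.?[0-9]+$", num)) {
    pct <- as.numeric(num)
    if (pct < 0 || pct > 100) {
      abort(sprintf("numeric positivity '%s' is outside [0, 100]%%", term),
            "ihcdiff_range_error")
    }
    return(pct / 100)
  }
  abort(sprintf(
    "unknown positivity term '%s'; expected one of: %s, or a numeric percentage",
    term, paste(sQuote(names(.positivity_vocabulary)), collapse = ", ")),
    "ihcdiff_vocabulary_error")
}

.positivity_vocabulary <- list(
  "always" = 0.95,
  "often" = 0.75,
  "in about a half of cases" = 0.50,
  "about half" = 0.50,
  "half" = 0.50,
  "seldom" = 0.30,
  "rarely" = 0.10,
  "occasionally" = 0.10,
  "rarely/occasionally" = 0.10,
  "rarely/ occasionally" = 0.10,
  "never" = 0
)

#' Render a positivity fraction as a display grade
#'
#' Grades mirror the conventional five-level IHC table rendering: `"++"` for
#' 75--100% positivity, `"+"` for 50--74%, `"+/-"` for 30--49%, `"-/+"` for
#' 10--29% and `"-"` for 0--9%. Bins are half-open on the percent scale
#' (`[75, 100]`, `[50, 75)`, `[30, 50)`, `[10, 30)`, `[0, 10)`) so every
#' fraction in `[0, 1]` receives exactly one grade.
#'
#' @param value Probability fraction in `[0, 1]` (vectorised).
#' @param ascii If `TRUE` (default) return ASCII-safe labels
#'   (`"+/-"`, `"-/+"`, `"--"`) suitable for plain-text files; otherwise the
#'   typographic forms with minus signs and an en dash.
#' @return Character vector of grade labels.
#' @examples
#' display_grade(0.80)  # "++"
#' display_grade(0.10)  # "-/+"
#' @export
display_grade <- function(value, ascii = TRUE) {
  if (!is.numeric(value) || anyNA(value)) {
    abort("`value` must be numeric without NAs", "ihcdiff_argument_error")
  }
  if (any(value < 0 | value > 1)) {
    abort("positivity values must lie in [0, 1]", "ihcdiff_range_error")
  }
  labels <- if (ascii) {
    c("--", "-/+", "+/-", "+", "++")
  } else {
    c("\u2013", "\u2212/+", "+/\u2212", "+", "++")
  }
  pct <- value * 100
  idx <- findInterval(pct, c(0, 10, 30, 50, 75))
  labels[idx]
}

#' Average positivity values from several sources
#'
#' When sources disagree on a marker's positivity the knowledge base stores
#' the unweighted arithmetic mean of the source values; the individual
#' sources are kept for audit.
#'
#' @param values Non-empty numeric vector of probability fractions.
#' @return A `positivity_entry`: list with `value` (the mean) and
#'   `source_values` (the input).
#' @examples
#' merge_source_values(c(0.95, 0.75))$value  # 0.85
#' @export
merge_source_values <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    abort("`values` must be a non-empty numeric vector without NAs",
          "ihcdiff_argument_error")
  }
  if (any(values < 0 | values > 1)) {
    abort("source positivity values must lie in [0, 1]", "ihcdiff_range_error")
  }
  structure(list(value = mean(values), source_values = as.numeric(values)),
            class = "positivity_entry")
}

# -- antibody registry ---------------------------------------------------

#' Build an antibody registry
#'
#' @param canonical_name Character vector of unique canonical antibody names.
#' @param synonyms List of character vectors (or a semicolon-separated
#'   character vector), one element per antibody; may be empty.
#' @param prognostic_only Logical vector: markers informative about prognosis
#'   or therapy (e.g. EGFR, p53) rather than tumour origin; these are
#'   stripped before origin-oriented evaluation.
#' @return A data frame of class `antibody_registry` with columns
#'   `canonical_name`, `synonyms` (list column) and `prognostic_only`.
#' @export
antibody_registry <- function(canonical_name,
                              synonyms = vector("list", length(canonical_name)),
                              prognostic_only = rep(FALSE, length(canonical_name))) {
  canonical_name <- as.character(canonical_name)
  if (any(is.na(canonical_name) | canonical_name == "")) {
    abort("canonical names must be non-empty", "ihcdiff_argument_error")
  }
  if (is.character(synonyms)) {
    synonyms <- strsplit(synonyms, ";", fixed = TRUE)
  }
  synonyms <- lapply(synonyms, function(s) {
    s <- trimws(as.character(s))
    s[nzchar(s)]
  })
  reg <- data.frame(canonical_name = canonical_name,
                    prognostic_only = as.logical(prognostic_only),
                    stringsAsFactors = FALSE)
  reg$synonyms <- synonyms
  class(reg) <- c("antibody_registry", "data.frame")
  check_registry_integrity(reg)
  reg
}

# Normalise an antibody label for matching: case-insensitive, trimmed,
# internal whitespace collapsed, and "-", "/", " " treated as equivalent
# (removable) separators so "TTF1", "TTF-1" and "ttf 1" all agree.
normalize_antibody_name <- function(name) {
  x <- tolower(trimws(as.character(name)))
  x <- gsub("\\s+", " ", x)
  gsub("[-/ ]", "", x)
}

check_registry_integrity <- function(registry) {
  canon_norm <- normalize_antibody_name(registry$canonical_name)
  if (anyDuplicated(canon_norm)) {
    abort(sprintf("duplicate canonical antibody name(s): %s",
                  paste(unique(registry$canonical_name[duplicated(canon_norm)]),
                        collapse = ", ")),
          "ihcdiff_registry_error")
  }
  syn_norm <- lapply(registry$synonyms, normalize_antibody_name)
  flat <- unlist(syn_norm, use.names = FALSE)
  owner <- rep(registry$canonical_name, lengths(syn_norm))
  if (length(flat)) {
    # a synonym may not map to two canonical names, nor shadow a canonical name
    dup <- tapply(owner, flat, function(o) length(unique(o)))
    if (any(dup > 1)) {
      abort(sprintf("synonym(s) mapped to multiple antibodies: %s",
                    paste(names(dup)[dup > 1], collapse = ", ")),
            "ihcdiff_registry_error")
    }
    clash <- flat %in% canon_norm & owner != registry$canonical_name[
      match(flat, canon_norm)]
    if (any(clash)) {
      abort(sprintf("synonym(s) collide with canonical names: %s",
                    paste(unique(flat[clash]), collapse = ", ")),
            "ihcdiff_registry_error")
    }
  }
  invisible(registry)
}

#' Resolve an antibody name to its canonical form
#'
#' Matching is case-insensitive after normalisation (trimming, whitespace
#' collapsing, and treating hyphen/space/slash as equivalent separators).
#' Canonical names take precedence over synonyms.
#'
#' @param name Character scalar (or vector) to resolve.
#' @param registry An [antibody_registry()].
#' @return Canonical name(s).
#' @examples
#' reg <- antibody_registry("TTF-1", synonyms = list("NKX2-1"))
#' resolve_antibody("ttf1", reg)    # "TTF-1"
#' resolve_antibody("NKX2-1", reg)  # "TTF-1"
#' @export
resolve_antibody <- function(name, registry) {
  check_registry_integrity(registry)
  canon_norm <- normalize_antibody_name(registry$canonical_name)
  syn_norm <- lapply(registry$synonyms, normalize_antibody_name)
  flat <- unlist(syn_norm, use.names = FALSE)
  owner_idx <- rep(seq_len(nrow(registry)), lengths(syn_norm))

  vapply(as.character(name), function(nm) {
    key <- normalize_antibody_name(nm)
    i <- match(key, canon_norm)
    if (!is.na(i)) return(registry$canonical_name[i])
    j <- match(key, flat)
    if (!is.na(j)) return(registry$canonical_name[owner_idx[j]])
    near <- registry$canonical_name[
      order(utils::adist(key, canon_norm, ignore.case = TRUE))]
    abort(sprintf("unknown antibody '%s'; nearest registered names: %s",
                  nm, paste(utils::head(near, 3L), collapse = ", ")),
          "ihcdiff_unknown_antibody_error", antibody = nm)
  }, character(1), USE.NAMES = FALSE)
}

# -- knowledge base ------------------------------------------------------

#' Construct an IHC knowledge base
#'
#' The knowledge base holds a disease registry, an antibody registry and a
#' sparse map of positivity fractions: the probability that a marker stains
#' positive in a disease, `P(marker positive | disease)`. Missing
#' (disease, antibody) pairs are allowed and mean "not profiled".
#'
#' @param diseases Data frame with columns `disease_id`, `display_name`,
#'   `organ`, `category` and `equivalence_group` (`NA` when the disease has
#'   no location-only variants).
#' @param antibodies An [antibody_registry()].
#' @param profiles Data frame with columns `disease_id`, `antibody`
#'   (canonical) and `value` (fraction in `[0, 1]`).
#' @return An object of class `ihc_kb`.
#' @export
ihc_kb <- function(diseases, antibodies, profiles) {
  diseases <- as.data.frame(diseases, stringsAsFactors = FALSE)
  required <- c("disease_id", "display_name", "organ", "category")
  missing_cols <- setdiff(required, names(diseases))
  if (length(missing_cols)) {
    abort(sprintf("disease table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          "ihcdiff_argument_error")
  }
  if (is.null(diseases$equivalence_group)) diseases$equivalence_group <- NA_character_
  if (anyDuplicated(diseases$disease_id)) {
    abort(sprintf("duplicate disease_id: %s",
                  paste(unique(diseases$disease_id[duplicated(diseases$disease_id)]),
                        collapse = ", ")),
          "ihcdiff_integrity_error")
  }
  bad_cat <- setdiff(unique(diseases$category), disease_categories())
  if (length(bad_cat)) {
    abort(sprintf("unknown disease category: %s",
                  paste(bad_cat, collapse = ", ")),
          "ihcdiff_integrity_error")
  }
  profiles <- as.data.frame(profiles, stringsAsFactors = FALSE)
  if (nrow(profiles)) {
    orphan_d <- setdiff(profiles$disease_id, diseases$disease_id)
    orphan_a <- setdiff(profiles$antibody, antibodies$canonical_name)
    if (length(orphan_d) || length(orphan_a)) {
      abort(sprintf("profile entries reference unknown disease(s) [%s] or antibody(ies) [%s]",
                    paste(orphan_d, collapse = ", "),
                    paste(orphan_a, collapse = ", ")),
            "ihcdiff_integrity_error")
    }
    if (any(profiles$value < 0 | profiles$value > 1)) {
      abort("profile values must lie in [0, 1]", "ihcdiff_range_error")
    }
    if (anyDuplicated(profiles[c("disease_id", "antibody")])) {
      abort("duplicate (disease, antibody) profile entries", "ihcdiff_integrity_error")
    }
  }
  structure(list(diseases = diseases, antibodies = antibodies,
                 profiles = profiles),
            class = "ihc_kb")
}

#' The closed set of disease category labels
#' @return Character vector of the five category labels used in reports.
#' @export
disease_categories <- function() {
  c("primary carcinoma", "metastatic carcinoma", "benign (normal) lesion",
    "benign mesenchymal tumour", "malignant mesenchymal tumour")
}

#' @export
print.ihc_kb <- function(x, ...) {
  cat(sprintf("<ihc_kb> %d diseases x %d antibodies, %d profiled entries\n",
              nrow(x$diseases), nrow(x$antibodies), nrow(x$profiles)))
  invisible(x)
}

# Dense disease x antibody positivity matrix (NA = not profiled).
profile_matrix <- function(kb) {
  m <- matrix(NA_real_, nrow = nrow(kb$diseases), ncol = nrow(kb$antibodies),
              dimnames = list(kb$diseases$disease_id,
                              kb$antibodies$canonical_name))
  if (nrow(kb$profiles)) {
    m[cbind(match(kb$profiles$disease_id, rownames(m)),
            match(kb$profiles$antibody, colnames(m)))] <- kb$profiles$value
  }
  m
}

# -- file I/O ------------------------------------------------------------

#' Read an antibody registry from TSV or JSON
#'
#' TSV columns: `canonical_name`, `synonyms` (semicolon-separated, may be
#' empty) and `prognostic_only` (`true`/`false`). The JSON form is an array
#' of objects with the same field names.
#'
#' @param path File path; format inferred from the `.json` extension.
#' @return An [antibody_registry()].
#' @export
read_antibody_registry <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("registry file not found: %s", path), "ihcdiff_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    syn <- rec$synonyms
    if (is.null(syn)) syn <- vector("list", nrow(rec))
    return(antibody_registry(rec$canonical_name, syn,
                             isTRUE_vec(rec$prognostic_only, nrow(rec))))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c("canonical_name", "synonyms", "prognostic_only")
  if (!all(need %in% names(tab))) {
    abort(sprintf("registry file %s must have columns: %s", path,
                  paste(need, collapse = ", ")), "ihcdiff_load_error")
  }
  antibody_registry(tab$canonical_name, tab$synonyms,
                    tolower(tab$prognostic_only) %in% c("true", "t", "1", "yes"))
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(FALSE, n) else as.logical(x) %in% TRUE
}

#' Load a knowledge base from a wide profile TSV plus an antibody registry
#'
#' The profile file is a wide UTF-8 TSV whose header row is
#' `disease_id`, `display_name`, `organ`, `category`, `equivalence_group`
#' followed by one column per antibody. Cells hold a numeric percentage, a
#' vocabulary term (see [encode_positivity_term()]) or are blank (marker not
#' profiled for that disease). Antibody column headers are resolved through
#' the registry before storage.
#'
#' @param profile_source Path to the wide profile TSV.
#' @param registry_source Path to the registry TSV/JSON, or an
#'   [antibody_registry()] object.
#' @return An [ihc_kb()].
#' @export
load_knowledge_base <- function(profile_source, registry_source) {
  registry <- if (inherits(registry_source, "antibody_registry")) {
    registry_source
  } else {
    read_antibody_registry(registry_source)
  }
  if (!file.exists(profile_source)) {
    abort(sprintf("profile file not found: %s", profile_source), "ihcdiff_io_error")
  }
  tab <- utils::read.delim(profile_source, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  meta_cols <- c("disease_id", "display_name", "organ", "category",
                 "equivalence_group")
  if (!identical(names(tab)[seq_along(meta_cols)], meta_cols)) {
    abort(sprintf(
      "malformed header in %s: first columns must be %s",
      profile_source, paste(meta_cols, collapse = ", ")), "ihcdiff_load_error")
  }
  if (anyDuplicated(tab$disease_id)) {
    abort(sprintf("duplicate disease_id in %s: %s", profile_source,
                  paste(unique(tab$disease_id[duplicated(tab$disease_id)]),
                        collapse = ", ")),
          "ihcdiff_load_error")
  }
  ab_cols <- setdiff(names(tab), meta_cols)
  canon <- tryCatch(resolve_antibody(ab_cols, registry),
                    ihcdiff_unknown_antibody_error = function(e) {
                      abort(sprintf("unresolvable antibody column in %s: %s",
                                    profile_source, conditionMessage(e)),
                            "ihcdiff_load_error")
                    })
  rows <- list()
  for (j in seq_along(ab_cols)) {
    cell <- tab[[ab_cols[j]]]
    keep <- !is.na(cell) & nzchar(trimws(cell))
    if (!any(keep)) next
    vals <- vapply(which(keep), function(i) {
      tryCatch(encode_positivity_term(cell[i]), ihcdiff_error = function(e) {
        abort(sprintf("bad cell at row %d (disease '%s'), column '%s': %s",
                      i, tab$disease_id[i], ab_cols[j], conditionMessage(e)),
              "ihcdiff_load_error")
      })
    }, numeric(1))
    rows[[j]] <- data.frame(disease_id = tab$disease_id[keep],
                            antibody = canon[j], value = vals,
                            stringsAsFactors = FALSE)
  }
  profiles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(disease_id = character(), antibody = character(),
               value = numeric(), stringsAsFactors = FALSE)
  tab$equivalence_group[!nzchar(trimws(tab$equivalence_group))] <- NA_character_
  ihc_kb(tab[meta_cols], registry, profiles)
}

#' Write a knowledge base to a wide profile TSV
#'
#' Numeric rendering writes positivity as percentages (loss-free to nine
#' decimals; `load_knowledge_base()` on the output reproduces the input).
#' Grade rendering writes the ASCII display grades instead, mirroring the
#' five-level table view. Missing entries are written as blank cells.
#'
#' @param kb An [ihc_kb()].
#' @param destination Output file path.
#' @param rendering `"numeric"` (round-trippable) or `"grade"`.
#' @export
write_knowledge_base <- function(kb, destination, rendering = c("numeric", "grade")) {
  rendering <- match.arg(rendering)
  m <- profile_matrix(kb)
  cells <- matrix("", nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  filled <- !is.na(m)
  cells[filled] <- if (rendering == "numeric") {
    formatC(m[filled] * 100, format = "g", digits = 12)
  } else {
    display_grade(m[filled], ascii = TRUE)
  }
  meta <- kb$diseases[c("disease_id", "display_name", "organ", "category",
                        "equivalence_group")]
  meta$equivalence_group[is.na(meta$equivalence_group)] <- ""
  out <- cbind(meta, as.data.frame(cells, stringsAsFactors = FALSE,
                                   check.names = FALSE))
  con <- tryCatch(file(destination, "w", encoding = "UTF-8"),
                  error = function(e) abort(
                    sprintf("cannot write to %s: %s", destination,
                            conditionMessage(e)), "ihcdiff_io_error"))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "")
  invisible(destination)
}

#' Write an antibody registry to TSV
#' @param registry An [antibody_registry()].
#' @param destination Output file path.
#' @export
write_antibody_registry <- function(registry, destination) {
  out <- data.frame(
    canonical_name = registry$canonical_name,
    synonyms = vapply(registry$synonyms, paste, character(1), collapse = ";"),
    prognostic_only = tolower(as.character(registry$prognostic_only)),
    stringsAsFactors = FALSE)
  utils::write.table(out, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(destination)
}

#' Quality-control a knowledge base
#'
#' Reports content findings without throwing: out-of-range values, orphan
#' profile keys, diseases with no profiled antibodies, antibodies profiled in
#' no disease, and synonym collisions in the registry. An empty result means
#' all structural invariants hold.
#'
#' @param kb An `ihc_kb` (or a structurally similar list, so defective
#'   hand-built objects can be inspected).
#' @return Data frame with columns `kind` and `detail`; zero rows when clean.
#' @export
validate_knowledge_base <- function(kb) {
  findings <- list()
  add <- function(kind, detail) {
    findings[[length(findings) + 1L]] <<- data.frame(
      kind = kind, detail = detail, stringsAsFactors = FALSE)
  }
  pr <- kb$profiles
  if (nrow(pr)) {
    bad <- pr$value < 0 | pr$value > 1
    for (i in which(bad)) {
      add("out-of-range", sprintf("(%s, %s) value %g", pr$disease_id[i],
                                  pr$antibody[i], pr$value[i]))
    }
    for (d in setdiff(unique(pr$disease_id), kb$diseases$disease_id)) {
      add("orphan-disease", d)
    }
    for (a in setdiff(unique(pr$antibody), kb$antibodies$canonical_name)) {
      add("orphan-antibody", a)
    }
  }
  for (d in setdiff(kb$diseases$disease_id, pr$disease_id)) {
    add("empty-profile", d)
  }
  for (a in setdiff(kb$antibodies$canonical_name, pr$antibody)) {
    add("unused-antibody", a)
  }
  syn_norm <- lapply(kb$antibodies$synonyms, normalize_antibody_name)
  flat <- unlist(syn_norm, use.names = FALSE)
  owner <- rep(kb$antibodies$canonical_name, lengths(syn_norm))
  if (length(flat)) {
    per_syn <- tapply(owner, flat, function(o) unique(o), simplify = FALSE)
    for (s in names(per_syn)[vapply(per_syn, length, integer(1)) > 1]) {
      add("synonym-collision",
          sprintf("'%s' claimed by %s", s, paste(per_syn[[s]], collapse = ", ")))
    }
  }
  if (length(findings)) do.call(rbind, findings) else
    data.frame(kind = character(), detail = character(), stringsAsFactors = FALSE)
}
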