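#' Specification for the synthetic knowledge base and case generator
#'
#' The generator emulates the statistical structure a curated IHC knowledge
#' base and a labelled tumour-of-unknown-origin case series are assumed to
#' have: positivity values restricted to the discrete curation vocabulary
#' \{0, 0.10, 0.30, 0.50, 0.75, 0.95\}, each disease carrying a small set of
#' near-specific markers (0.95 in the disease, at most 0.10 wherever they
#' are profiled elsewhere), panels of 1--13 markers averaging 6.8 per case,
#' and binary results sampled from the profile with a configurable
#' atypicality (contradiction) rate.
#'
#' @param n_diseases Number of diseases (default 20).
#' @param n_antibodies Number of antibodies (default 60).
#' @param markers_per_disease Length-2 integer range of profiled markers per
#'   disease (default `c(13, 20)`, so every profile can support a full-size
#'   panel).
#' @param specific_markers_per_disease Markers per disease set to 0.95 in
#'   that disease and kept at or below 0.10 in every other profile
#'   (default 2).
#' @param panel_size_mean Target mean panel size (default 6.8).
#' @param panel_size_range Length-2 integer range of panel sizes
#'   (default `c(1, 13)`).
#' @param atypicality_rate Probability that a sampled result is flipped to
#'   contradict its profile (default 0.1).
#' @param vocabulary Discrete positivity values profiles are drawn from
#'   (default the full six-value curation vocabulary). Restricting it to
#'   `c(0, 0.95)` yields maximally distinctive profiles, the regime in which
#'   the true diagnosis is near-always recoverable at zero noise.
#' @param exact_sampling If `TRUE`, Bernoulli sampling probabilities are
#'   clipped to exactly 0 or 1 (a profiled 0.95 always stains positive, a 0
#'   never does), so with `atypicality_rate = 0` every result matches its
#'   profile sign: the noise-free limit. Default `FALSE` (sample at the
#'   stored positivity).
#' @param seed Integer seed; all generation is reproducible under it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_diseases = 20L, n_antibodies = 60L,
                           markers_per_disease = c(13L, 20L),
                           specific_markers_per_disease = 2L,
                           panel_size_mean = 6.8,
                           panel_size_range = c(1L, 13L),
                           atypicality_rate = 0.1,
                           vocabulary = positivity_vocabulary_values(),
                           exact_sampling = FALSE,
                           seed = 1L) {
  n_diseases <- as.integer(n_diseases)
  n_antibodies <- as.integer(n_antibodies)
  if (is.na(n_diseases) || n_diseases < 1L || is.na(n_antibodies) ||
      n_antibodies < 1L) {
    abort("n_diseases and n_antibodies must be positive integers",
          "ihcdiff_argument_error")
  }
  s <- as.integer(specific_markers_per_disease)
  if (s < 0L || n_diseases * s > n_antibodies) {
    abort(sprintf(
      "infeasible spec: %d diseases x %d specific markers exceed %d antibodies",
      n_diseases, s, n_antibodies), "ihcdiff_argument_error")
  }
  markers_per_disease <- as.integer(markers_per_disease)
  if (length(markers_per_disease) != 2L ||
      markers_per_disease[1] < s ||
      markers_per_disease[2] > n_antibodies ||
      markers_per_disease[1] > markers_per_disease[2]) {
    abort("invalid markers_per_disease range", "ihcdiff_argument_error")
  }
  panel_size_range <- as.integer(panel_size_range)
  if (length(panel_size_range) != 2L || panel_size_range[1] < 1L ||
      panel_size_range[2] > n_antibodies ||
      panel_size_range[1] > panel_size_range[2]) {
    abort("panel_size_range must lie within [1, n_antibodies]",
          "ihcdiff_argument_error")
  }
  if (atypicality_rate < 0 || atypicality_rate > 1) {
    abort("atypicality_rate must lie in [0, 1]", "ihcdiff_range_error")
  }
  vocabulary <- sort(unique(as.numeric(vocabulary)))
  if (length(vocabulary) == 0L || any(vocabulary < 0 | vocabulary > 1)) {
    abort("vocabulary values must lie in [0, 1]", "ihcdiff_range_error")
  }
  structure(list(n_diseases = n_diseases, n_antibodies = n_antibodies,
                 markers_per_disease = markers_per_disease,
                 specific_markers_per_disease = s,
                 panel_size_mean = panel_size_mean,
                 panel_size_range = panel_size_range,
                 atypicality_rate = atypicality_rate,
                 vocabulary = vocabulary,
                 exact_sampling = isTRUE(exact_sampling),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# The discrete curation vocabulary of positivity fractions.
positivity_vocabulary_values <- function() c(0, 0.10, 0.30, 0.50, 0.75, 0.95)

#' Generate a synthetic knowledge base
#'
#' Every positivity value is drawn from the curation vocabulary. Each
#' disease is assigned `specific_markers_per_disease` disjoint markers at
#' 0.95; wherever one of those markers is profiled in another disease its
#' value is drawn from \{0, 0.10\}. Remaining profiled markers take values
#' uniform over the vocabulary. Output is deterministic under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return An [ihc_kb()].
#' @export
generate_knowledge_base <- function(spec) {
  with_local_seed(spec$seed, {
    nd <- spec$n_diseases; na <- spec$n_antibodies
    s <- spec$specific_markers_per_disease
    d_ids <- sprintf("D%03d", seq_len(nd))
    a_ids <- sprintf("MK%03d", seq_len(na))
    vocab <- spec$vocabulary
    # specific markers of other diseases stay at or below 0.10
    vocab_low <- vocab[vocab <= 0.10]
    if (length(vocab_low) == 0L) vocab_low <- 0
    # disjoint specific-marker assignment
    specific <- if (s > 0) {
      pool <- sample(a_ids, nd * s)
      split(pool, rep(seq_len(nd), each = s))
    } else rep(list(character()), nd)
    specific_all <- unlist(specific, use.names = FALSE)
    rows <- vector("list", nd)
    for (i in seq_len(nd)) {
      m <- sample(spec$markers_per_disease[1]:spec$markers_per_disease[2], 1)
      own <- specific[[i]]
      others <- sample(setdiff(a_ids, own), m - length(own))
      markers <- c(own, others)
      foreign <- others %in% specific_all
      draw <- function(v, n) v[sample.int(length(v), n, replace = TRUE)]
      vals <- c(rep(0.95, length(own)),
                ifelse(foreign,
                       draw(vocab_low, length(others)),
                       draw(vocab, length(others))))
      rows[[i]] <- data.frame(disease_id = d_ids[i], antibody = markers,
                              value = vals, stringsAsFactors = FALSE)
    }
    categories <- sample(disease_categories(), nd, replace = TRUE)
    organs <- sample(c("lung", "liver", "kidney", "stomach", "colon",
                       "breast", "soft tissue", "lymph node"),
                     nd, replace = TRUE)
    diseases <- data.frame(disease_id = d_ids,
                           display_name = paste("synthetic neoplasm", d_ids),
                           organ = organs, category = categories,
                           equivalence_group = NA_character_,
                           stringsAsFactors = FALSE)
    ihc_kb(diseases, antibody_registry(a_ids), do.call(rbind, rows))
  })
}

# Panel sizes: 1 + Binomial(12, p) matched to the target mean, truncated to
# the spec range. Bounded, integer-valued and fully described by (mean, range).
sample_panel_sizes <- function(n, spec) {
  lo <- spec$panel_size_range[1]; hi <- spec$panel_size_range[2]
  trials <- hi - lo
  p <- if (trials > 0) (spec$panel_size_mean - lo) / trials else 0
  p <- min(max(p, 0), 1)
  pmin(pmax(lo + stats::rbinom(n, trials, p), lo), hi)
}

#' Generate labelled synthetic cases from a knowledge base
#'
#' Per case: a true disease drawn uniformly; a panel size drawn from a
#' shifted binomial matched to `spec$panel_size_mean` and truncated to
#' `spec$panel_size_range`; the panel always contains the disease's specific
#' markers when the size permits, topped up with other profiled markers;
#' each result is Bernoulli with the profiled positivity and then flipped
#' with probability `spec$atypicality_rate`.
#'
#' @param kb An [ihc_kb()] (typically from [generate_knowledge_base()]).
#' @param n_cases Number of cases.
#' @param spec The [synthetic_spec()]; case generation is seeded from
#'   `spec$seed` (offset so it does not replay the KB stream).
#' @return List of [validation_case()] objects.
#' @export
generate_cases <- function(kb, n_cases, spec) {
  if (n_cases < 1L) abort("n_cases must be >= 1", "ihcdiff_argument_error")
  m <- profile_matrix(kb)
  profiled <- apply(m, 1, function(r) colnames(m)[!is.na(r)],
                    simplify = FALSE)
  if (min(lengths(profiled)) < spec$panel_size_range[1]) {
    abort("panel size range infeasible: a disease profiles fewer markers than the minimum panel size",
          "ihcdiff_argument_error")
  }
  # specific markers = profiled at 0.95 in this disease, <= 0.10 elsewhere
  spec_markers <- lapply(rownames(m), function(d) {
    v <- m[d, ]
    cand <- names(v)[!is.na(v) & v >= 0.95]
    others <- m[setdiff(rownames(m), d), cand, drop = FALSE]
    cand[apply(others, 2, function(x) all(is.na(x) | x <= 0.10))]
  })
  names(spec_markers) <- rownames(m)
  with_local_seed(spec$seed + 1L, {
    d_idx <- sample.int(nrow(m), n_cases, replace = TRUE)
    sizes <- sample_panel_sizes(n_cases, spec)
    lapply(seq_len(n_cases), function(i) {
      d <- rownames(m)[d_idx[i]]
      avail <- profiled[[d]]
      k <- min(sizes[i], length(avail))
      own <- spec_markers[[d]]
      markers <- if (k <= length(own)) {
        sample(own, k)
      } else {
        c(own, sample(setdiff(avail, own), k - length(own)))
      }
      p <- m[d, markers]
      if (spec$exact_sampling) p <- as.numeric(p >= 0.5)
      res <- stats::rbinom(k, 1L, p) == 1L
      flip <- stats::runif(k) < spec$atypicality_rate
      res <- xor(res, flip)
      cat_lab <- kb$diseases$category[match(d, kb$diseases$disease_id)]
      organ <- kb$diseases$organ[match(d, kb$diseases$disease_id)]
      validation_case(sprintf("case%05d", i),
                      structure(stats::setNames(res, markers),
                                class = "case_panel"),
                      d, cat_lab, organ)
    })
  })
}

#' Write a matched synthetic fixture bundle to disk
#'
#' Emits a knowledge-base TSV, an antibody registry TSV (with a few synonym
#' entries plus EGFR and p53 flagged as prognostic-only), a long-format case
#' TSV, and a JSON manifest recording the generator settings. About a third
#' of case panels receive an extra prognostic-marker result so downstream
#' filtering has something to strip. All files load cleanly through
#' [load_knowledge_base()] and [read_cases()] and regenerate byte-identically
#' from the manifest.
#'
#' @param destination Directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @param n_cases Number of cases (default 200).
#' @return Invisibly, the manifest path.
#' @export
generate_fixture_bundle <- function(destination, spec = synthetic_spec(),
                                    n_cases = 200L) {
  ok <- dir.exists(destination) || dir.create(destination, recursive = TRUE)
  if (!ok) abort(sprintf("cannot create %s", destination), "ihcdiff_io_error")
  kb <- generate_knowledge_base(spec)
  cases <- generate_cases(kb, n_cases, spec)

  prognostic <- c("EGFR", "p53")
  syn <- vector("list", nrow(kb$antibodies))
  syn[1:3] <- list("KL-1a", "KL-2a", "KL-3a")  # a few alias entries
  registry <- antibody_registry(
    c(kb$antibodies$canonical_name, prognostic),
    c(syn, list(character(), "TP53")),
    c(kb$antibodies$prognostic_only, TRUE, TRUE))
  kb$antibodies <- registry[seq_len(nrow(kb$antibodies)), ]
  class(kb$antibodies) <- c("antibody_registry", "data.frame")

  cases <- with_local_seed(spec$seed + 2L, {
    lapply(cases, function(cs) {
      if (stats::runif(1) < 1 / 3) {
        extra <- sample(prognostic, 1)
        cs$panel <- structure(
          c(cs$panel, stats::setNames(stats::runif(1) < 0.5, extra)),
          class = "case_panel")
      }
      cs
    })
  })

  kb_path <- file.path(destination, "knowledge_base.tsv")
  reg_path <- file.path(destination, "registry.tsv")
  case_path <- file.path(destination, "cases.tsv")
  manifest_path <- file.path(destination, "manifest.json")
  write_knowledge_base(kb, kb_path, rendering = "numeric")
  write_antibody_registry(registry, reg_path)
  write_cases(cases, case_path)
  jsonlite::write_json(
    list(spec = unclass(spec), n_cases = n_cases,
         files = list(knowledge_base = basename(kb_path),
                      registry = basename(reg_path),
                      cases = basename(case_path))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest_path)
}
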