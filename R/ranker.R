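#' Ranker configuration
#'
#' Settings for the diagnosis presumption algorithm.
#'
#' @param floor Clip bound for per-marker probabilities: every positivity is
#'   clipped to `[floor, 1 - floor]` before entering the likelihood product,
#'   so a single atypical result ("never"-encoded marker staining positive)
#'   penalises a disease instead of excluding it outright. Default 0.01.
#' @param missing_policy How to treat a panel marker that is not profiled for
#'   a disease: `"impute"` (default) substitutes `impute_value`; `"skip"`
#'   drops the marker from that disease's product. Skipping is biased when
#'   profile coverage differs between diseases, because products over fewer
#'   factors are systematically larger.
#' @param impute_value Positivity used under the impute policy; 0.5 is
#'   uninformative (a positive and a negative result weigh the same).
#' @param prior `"uniform"` (the pre-test incidence is taken as negligible,
#'   so it cancels in normalisation) or a named numeric vector of
#'   disease-level prior probabilities summing to 1.
#' @param top_k Number of diagnoses to return; the conventional differential
#'   length is 10.
#' @param score_mode Which score orders the differential: `"posterior"`
#'   (default; normalised across scored diseases) or `"concordance"` (the
#'   per-disease geometric-mean fit, independent of the other candidates).
#' @return A list of class `ranker_config`.
#' @export
ranker_config <- function(floor = 0.01,
                          missing_policy = c("impute", "skip"),
                          impute_value = 0.5,
                          prior = "uniform",
                          top_k = 10L,
                          score_mode = c("posterior", "concordance")) {
  missing_policy <- match.arg(missing_policy)
  score_mode <- match.arg(score_mode)
  stopifnot_scalar_number(floor, "floor")
  stopifnot_scalar_number(impute_value, "impute_value")
  if (floor <= 0 || floor >= 0.5) {
    abort("`floor` must satisfy 0 < floor < 0.5", "ihcdiff_argument_error")
  }
  if (impute_value < 0 || impute_value > 1) {
    abort("`impute_value` must lie in [0, 1]", "ihcdiff_range_error")
  }
  if (!(identical(prior, "uniform"))) {
    if (!is.numeric(prior) || is.null(names(prior)) || any(prior < 0)) {
      abort("`prior` must be \"uniform\" or a named non-negative numeric vector",
            "ihcdiff_argument_error")
    }
    if (abs(sum(prior) - 1) > 1e-9) {
      abort("explicit priors must sum to 1", "ihcdiff_argument_error")
    }
  }
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L) {
    abort("`top_k` must be a positive integer", "ihcdiff_argument_error")
  }
  structure(list(floor = floor, missing_policy = missing_policy,
                 impute_value = impute_value, prior = prior,
                 top_k = top_k, score_mode = score_mode),
            class = "ranker_config")
}

#' Construct a case panel of binary IHC results
#'
#' @param results Named logical vector (`TRUE` = positive) or a named
#'   character/numeric vector of result tokens (`+`, `-`, `pos`, `neg`,
#'   `positive`, `negative`, `1`, `0`), keyed by antibody name.
#' @param registry Optional [antibody_registry()]; when given, names are
#'   resolved to canonical form.
#' @return Named logical vector of class `case_panel`.
#' @export
case_panel <- function(results, registry = NULL) {
  if (length(results) == 0L || is.null(names(results)) ||
      any(!nzchar(names(results)))) {
    abort("a case panel needs at least one named marker result",
          "ihcdiff_argument_error")
  }
  vals <- parse_result_tokens(results)
  nms <- names(results)
  if (!is.null(registry)) nms <- resolve_antibody(nms, registry)
  if (anyDuplicated(nms)) {
    abort(sprintf("duplicate panel marker(s) after resolution: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", ")),
          "ihcdiff_argument_error")
  }
  structure(stats::setNames(vals, nms), class = "case_panel")
}

# Accepts logicals, 0/1, and the common positive/negative spellings;
# anything else is an inconclusive token.
parse_result_tokens <- function(results) {
  if (is.logical(results)) {
    if (anyNA(results)) abort("panel results may not be NA",
                              "ihcdiff_inconclusive_error")
    return(as.vector(results))
  }
  tok <- tolower(trimws(as.character(results)))
  pos <- tok %in% c("+", "pos", "positive", "1", "true")
  neg <- tok %in% c("-", "neg", "negative", "0", "false")
  if (any(!pos & !neg)) {
    abort(sprintf("inconclusive result token(s): %s",
                  paste(unique(tok[!pos & !neg]), collapse = ", ")),
          "ihcdiff_inconclusive_error")
  }
  pos
}

#' Per-marker likelihood factor
#'
#' The factor a single marker contributes to a disease's likelihood:
#' the clipped positivity `p' = min(max(p, floor), 1 - floor)` for a positive
#' result, `1 - p'` for a negative one. Under the skip policy a missing
#' positivity yields `NA` (no factor); under impute, `impute_value` is used
#' in place of the missing positivity.
#'
#' @param positivity Profiled positivity fraction, or `NA` if unprofiled.
#' @param outcome Logical: `TRUE` for a positive IHC result.
#' @param config A [ranker_config()].
#' @return Factor in `(0, 1)`, or `NA` when the marker is skipped.
#' @examples
#' cfg <- ranker_config(floor = 0.01)
#' marker_factor(0.9, FALSE, cfg)  # 0.1
#' marker_factor(0.0, TRUE, cfg)   # 0.01 (floored "never" entry)
#' @export
marker_factor <- function(positivity, outcome, config = ranker_config()) {
  p <- ifelse(is.na(positivity),
              if (config$missing_policy == "impute") config$impute_value else NA_real_,
              positivity)
  p <- pmin(pmax(p, config$floor), 1 - config$floor)
  ifelse(outcome, p, 1 - p)
}

#' Likelihood of a panel under one disease profile
#'
#' Markers are conditionally independent given the disease, so the panel
#' likelihood is the product of per-marker factors; it is accumulated as a
#' sum of logs.
#'
#' @param profile Named numeric vector of positivity fractions for one
#'   disease (names = canonical antibodies); markers absent from the profile
#'   are handled per the missing policy.
#' @param panel A [case_panel()].
#' @param config A [ranker_config()].
#' @return List with `log_likelihood`, `factors` (named, one per contributing
#'   marker) and `n_profiled` (markers scored from the profile rather than
#'   imputed).
#' @export
case_likelihood <- function(profile, panel, config = ranker_config()) {
  markers <- names(panel)
  pos <- unname(profile[markers])  # NA where unprofiled
  f <- marker_factor(pos, as.vector(panel), config)
  keep <- !is.na(f)
  if (!any(keep)) {
    abort("no panel marker overlaps this profile under the skip policy",
          "ihcdiff_no_overlap_error")
  }
  factors <- stats::setNames(f[keep], markers[keep])
  list(log_likelihood = sum(log(factors)),
       factors = factors,
       n_profiled = sum(keep & !is.na(pos)))
}

#' Normalise likelihoods into posteriors
#'
#' Bayes' rule with the given prior: `posterior_i = prior_i exp(ll_i) /
#' sum_j prior_j exp(ll_j)`, computed stably in log space (the maximum
#' log-likelihood is subtracted before exponentiating). With a uniform prior
#' the prior cancels.
#'
#' @param log_likelihoods Named numeric vector of log-likelihoods.
#' @param prior `"uniform"` or a named numeric vector covering all diseases.
#' @return Named numeric vector of posteriors summing to 1.
#' @export
normalize_posteriors <- function(log_likelihoods, prior = "uniform") {
  if (length(log_likelihoods) == 0L) {
    abort("no likelihoods to normalise", "ihcdiff_argument_error")
  }
  ll <- log_likelihoods
  if (identical(prior, "uniform")) {
    lp <- ll
  } else {
    missing_prior <- setdiff(names(ll), names(prior))
    if (length(missing_prior)) {
      abort(sprintf("prior does not cover disease(s): %s",
                    paste(missing_prior, collapse = ", ")),
            "ihcdiff_argument_error")
    }
    lp <- ll + log(prior[names(ll)])
  }
  w <- exp(lp - max(lp))
  stats::setNames(as.numeric(w / sum(w)), names(ll))
}

#' Concordance score of a factor set
#'
#' The geometric mean of the per-marker factors on the percent scale:
#' `100 * (prod f_i)^(1/n)`. Unlike the posterior it does not depend on the
#' other candidate diseases, so it reads as an absolute profile fit: 100
#' means every observed result matched the profile at full strength.
#'
#' @param factors Non-empty numeric vector of per-marker factors in `(0, 1]`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' concordance_score(c(0.9, 0.8, 0.7))  # 79.66
#' @export
concordance_score <- function(factors) {
  if (length(factors) == 0L || anyNA(factors)) {
    abort("`factors` must be non-empty and NA-free", "ihcdiff_argument_error")
  }
  100 * exp(mean(log(factors)))
}

#' Rank differential diagnoses for a binary IHC panel
#'
#' Scores every disease in the knowledge base against the panel (per-marker
#' factors multiplied under conditional independence), normalises posteriors
#' across the scored diseases, and returns the top `config$top_k` in
#' descending score order. Ties break by descending `n_profiled` (prefer the
#' better-evidenced disease), then ascending `disease_id`. Diseases with no
#' overlapping marker under the skip policy are omitted with a message.
#'
#' @param kb An [ihc_kb()].
#' @param panel A [case_panel()] (or a named vector accepted by it).
#' @param config A [ranker_config()].
#' @return Data frame with columns `rank`, `disease_id`, `display_name`,
#'   `log_likelihood`, `posterior`, `concordance`, `n_profiled`; per-marker
#'   factors are attached as the `"factors"` attribute (a named list).
#' @examples
#' kb <- ihc_kb(
#'   diseases = data.frame(disease_id = c("D1", "D2", "D3"),
#'                         display_name = c("D1", "D2", "D3"),
#'                         organ = "x", category = "primary carcinoma",
#'                         equivalence_group = NA),
#'   antibodies = antibody_registry(c("A", "B", "C")),
#'   profiles = data.frame(
#'     disease_id = rep(c("D1", "D2", "D3"), each = 3),
#'     antibody = rep(c("A", "B", "C"), 3),
#'     value = c(0.9, 0.8, 0.1, 0.5, 0.5, 0.5, 0.9, 0.1, 0.9)))
#' rank_diagnoses(kb, case_panel(c(A = "+", B = "-", C = "+")))
#' @export
rank_diagnoses <- function(kb, panel, config = ranker_config()) {
  if (!inherits(panel, "case_panel")) panel <- case_panel(panel)
  unknown <- setdiff(names(panel), kb$antibodies$canonical_name)
  if (length(unknown)) {
    # resolve through the registry (synonyms / separator variants)
    panel <- case_panel(stats::setNames(as.vector(panel), names(panel)),
                        registry = kb$antibodies)
  }
  m <- profile_matrix(kb)[, names(panel), drop = FALSE]
  outcome <- matrix(as.vector(panel), nrow = nrow(m), ncol = ncol(m),
                    byrow = TRUE)
  f <- matrix(marker_factor(as.vector(m), as.vector(outcome), config),
              nrow = nrow(m), dimnames = dimnames(m))
  contributes <- !is.na(f)
  scored <- rowSums(contributes) > 0
  if (!any(scored)) {
    abort("no disease shares a marker with this panel", "ihcdiff_empty_differential_error")
  }
  if (any(!scored)) {
    message(sprintf("omitting %d disease(s) with no overlapping marker: %s",
                    sum(!scored),
                    paste(rownames(m)[!scored], collapse = ", ")))
  }
  f <- f[scored, , drop = FALSE]
  lf <- log(f)
  lf[is.na(lf)] <- 0
  ll <- rowSums(lf)
  n_contrib <- rowSums(!is.na(f))
  n_profiled <- rowSums(!is.na(m[scored, , drop = FALSE]) & !is.na(f))
  posterior <- normalize_posteriors(ll, config$prior)
  concordance <- 100 * exp(ll / n_contrib)

  res <- data.frame(disease_id = rownames(f),
                    log_likelihood = ll,
                    posterior = as.numeric(posterior[rownames(f)]),
                    concordance = concordance,
                    n_profiled = as.integer(n_profiled),
                    stringsAsFactors = FALSE, row.names = NULL)
  score <- if (config$score_mode == "posterior") res$posterior else res$concordance
  ord <- order(-score, -res$n_profiled, res$disease_id)
  res <- res[ord, , drop = FALSE]
  res <- utils::head(res, config$top_k)
  res$rank <- seq_len(nrow(res))
  res$display_name <- kb$diseases$display_name[
    match(res$disease_id, kb$diseases$disease_id)]
  factors <- lapply(res$disease_id, function(d) {
    fd <- f[d, ]
    fd[!is.na(fd)]
  })
  names(factors) <- res$disease_id
  res <- res[c("rank", "disease_id", "display_name", "log_likelihood",
               "posterior", "concordance", "n_profiled")]
  rownames(res) <- NULL
  attr(res, "factors") <- factors
  class(res) <- c("ihc_differential", "data.frame")
  res
}

#' @export
print.ihc_differential <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$posterior <- signif(y$posterior, digits)
  y$concordance <- round(y$concordance, 1)
  y$log_likelihood <- round(y$log_likelihood, 3)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}
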