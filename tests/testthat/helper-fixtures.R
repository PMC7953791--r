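# Shared fixtures: a tiny hand-written KB, a random-KB generator for
# property tests, and a brute-force ranking oracle that forms each
# likelihood product directly (no logs) independent of the package's path.

tiny_kb <- function() {
  ihc_kb(
    diseases = data.frame(
      disease_id = c("D1", "D2", "D3"),
      display_name = c("Disease 1", "Disease 2", "Disease 3"),
      organ = c("lung", "lung", "stomach"),
      category = c("primary carcinoma", "metastatic carcinoma",
                   "primary carcinoma"),
      equivalence_group = NA_character_,
      stringsAsFactors = FALSE),
    antibodies = antibody_registry(c("A", "B", "C")),
    profiles = data.frame(
      disease_id = rep(c("D1", "D2", "D3"), each = 3),
      antibody = rep(c("A", "B", "C"), 3),
      value = c(0.9, 0.8, 0.1,
                0.5, 0.5, 0.5,
                0.9, 0.1, 0.9),
      stringsAsFactors = FALSE))
}

# Random sparse KB for property tests (values on a 0.05 grid, ~80% density).
random_kb <- function(n_diseases, n_antibodies, density = 0.8) {
  d_ids <- sprintf("D%02d", seq_len(n_diseases))
  a_ids <- sprintf("A%02d", seq_len(n_antibodies))
  grid <- expand.grid(disease_id = d_ids, antibody = a_ids,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  # every disease keeps at least one marker
  for (d in d_ids) {
    if (!any(keep & grid$disease_id == d)) {
      keep[which(grid$disease_id == d)[1]] <- TRUE
    }
  }
  grid <- grid[keep, ]
  grid$value <- sample(seq(0, 1, by = 0.05), nrow(grid), replace = TRUE)
  ihc_kb(
    diseases = data.frame(disease_id = d_ids, display_name = d_ids,
                          organ = "organ", category = "primary carcinoma",
                          equivalence_group = NA_character_,
                          stringsAsFactors = FALSE),
    antibodies = antibody_registry(a_ids),
    profiles = grid)
}

random_panel <- function(kb, size = NULL) {
  ab <- kb$antibodies$canonical_name
  if (is.null(size)) size <- sample(seq_along(ab), 1)
  nm <- sample(ab, size)
  structure(stats::setNames(runif(size) < 0.5, nm), class = "case_panel")
}

# Brute-force oracle: direct products, straight sort, no log space.
oracle_rank <- function(kb, panel, config = ranker_config()) {
  m <- profile_matrix(kb)
  rows <- lapply(rownames(m), function(d) {
    prod_f <- 1
    n_used <- 0L
    n_prof <- 0L
    for (a in names(panel)) {
      p <- m[d, a]
      if (is.na(p)) {
        if (config$missing_policy == "skip") next
        p <- config$impute_value
      } else {
        n_prof <- n_prof + 1L
      }
      p <- min(max(p, config$floor), 1 - config$floor)
      f <- if (panel[[a]]) p else 1 - p
      prod_f <- prod_f * f
      n_used <- n_used + 1L
    }
    if (n_used == 0L) return(NULL)
    data.frame(disease_id = d, likelihood = prod_f,
               concordance = 100 * prod_f^(1 / n_used),
               n_profiled = if (config$missing_policy == "skip") n_used else n_prof,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res) || nrow(res) == 0L) return(NULL)
  pri <- if (identical(config$prior, "uniform")) {
    rep(1 / nrow(res), nrow(res))
  } else {
    as.numeric(config$prior[res$disease_id])
  }
  res$posterior <- pri * res$likelihood / sum(pri * res$likelihood)
  score <- if (config$score_mode == "posterior") res$posterior else res$concordance
  res <- res[order(-score, -res$n_profiled, res$disease_id), ]
  res <- utils::head(res, config$top_k)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

# Top-k hit rate of a generated case list against its KB.
simulated_hit_rate <- function(kb, cases, k = 10L) {
  cfg <- ranker_config(top_k = max(10L, k))
  hits <- vapply(cases, function(cs) {
    r <- suppressMessages(rank_diagnoses(kb, cs$panel, cfg))
    is_hit(cs$true_disease_id, r, kb, k = k)
  }, logical(1))
  mean(hits)
}
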