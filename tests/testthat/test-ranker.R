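test_that("marker factors follow the complement, floor and imputation rules", {
  cfg <- ranker_config(floor = 0.01)
  expect_equal(marker_factor(0.9, FALSE, cfg), 0.1)
  expect_equal(marker_factor(0.9, TRUE, cfg), 0.9)
  expect_equal(marker_factor(0.0, TRUE, cfg), 0.01)   # floored "never"
  expect_equal(marker_factor(1.0, FALSE, cfg), 0.01)
  expect_equal(marker_factor(NA, TRUE, cfg), 0.5)     # impute default
  cfg_skip <- ranker_config(missing_policy = "skip")
  expect_true(is.na(marker_factor(NA, TRUE, cfg_skip)))
})

test_that("panel likelihood is the product of per-marker factors", {
  cfg <- ranker_config()
  profile <- c(A = 0.9, B = 0.2, C = 0.7)
  panel <- case_panel(c(A = TRUE, B = FALSE, C = TRUE))
  out <- case_likelihood(profile, panel, cfg)
  expect_equal(exp(out$log_likelihood), 0.9 * 0.8 * 0.7, tolerance = 1e-12)
  expect_equal(prod(out$factors), exp(out$log_likelihood), tolerance = 1e-9)
  expect_identical(out$n_profiled, 3L)

  flat <- case_likelihood(c(A = 0.5, B = 0.5, C = 0.5), panel, cfg)
  expect_equal(exp(flat$log_likelihood), 0.125, tolerance = 1e-12)

  # marker order cannot matter
  shuffled <- case_panel(c(C = TRUE, A = TRUE, B = FALSE))
  expect_equal(case_likelihood(profile, shuffled, cfg)$log_likelihood,
               out$log_likelihood)

  expect_error(
    case_likelihood(numeric(), panel, ranker_config(missing_policy = "skip")),
    class = "ihcdiff_no_overlap_error")
})

test_that("posterior normalisation is stable and prior-aware", {
  ll <- log(c(D1 = 0.018, D2 = 0.125, D3 = 0.729))
  post <- normalize_posteriors(ll)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  expect_equal(unname(post), c(0.018, 0.125, 0.729) / 0.872, tolerance = 1e-3)

  expect_equal(unname(normalize_posteriors(c(D = -5))), 1)

  # equal likelihoods pass the prior through
  pri <- c(D1 = 0.3, D2 = 0.5, D3 = 0.2)
  post <- normalize_posteriors(c(D1 = -1, D2 = -1, D3 = -1), prior = pri)
  expect_equal(unname(post), unname(pri), tolerance = 1e-12)

  # extreme log-likelihoods do not overflow
  post <- normalize_posteriors(c(a = -2000, b = -2001))
  expect_equal(sum(post), 1)
  expect_false(anyNA(post))

  expect_error(normalize_posteriors(numeric()), class = "ihcdiff_argument_error")
})

test_that("concordance is the geometric mean on the percent scale", {
  expect_equal(concordance_score(c(A = 0.9, B = 0.8, C = 0.7)),
               100 * 0.504^(1 / 3), tolerance = 1e-9)
  expect_equal(round(concordance_score(c(0.9, 0.8, 0.7)), 2), 79.58)
  expect_equal(concordance_score(0.5), 50)
  expect_equal(concordance_score(rep(0.99, 7)), 99, tolerance = 1e-9)
  expect_error(concordance_score(numeric()), class = "ihcdiff_argument_error")
})

test_that("the worked three-disease example ranks as expected", {
  kb <- tiny_kb()
  res <- rank_diagnoses(kb, case_panel(c(A = "+", B = "-", C = "+")))
  expect_identical(res$disease_id, c("D3", "D2", "D1"))
  expect_equal(exp(res$log_likelihood), c(0.729, 0.125, 0.018),
               tolerance = 1e-9)
  expect_equal(sum(res$posterior), 1, tolerance = 1e-9)
  expect_identical(res$rank, 1:3)
  # top_k larger than the candidate pool truncates to the pool
  res10 <- rank_diagnoses(kb, case_panel(c(A = "+", B = "-", C = "+")),
                          ranker_config(top_k = 10))
  expect_identical(nrow(res10), 3L)
})

test_that("ties break by n_profiled then ascending disease id", {
  kb <- ihc_kb(
    diseases = data.frame(disease_id = c("D2", "D1"),
                          display_name = c("D2", "D1"), organ = "x",
                          category = "primary carcinoma",
                          equivalence_group = NA_character_),
    antibodies = antibody_registry(c("A", "B")),
    profiles = data.frame(disease_id = c("D2", "D2", "D1", "D1"),
                          antibody = c("A", "B", "A", "B"),
                          value = c(0.9, 0.2, 0.9, 0.2)))
  res <- rank_diagnoses(kb, case_panel(c(A = "+", B = "-")))
  expect_identical(res$disease_id, c("D1", "D2"))  # identical profiles
})

test_that("ranking agrees with the brute-force product oracle", {
  set.seed(401)
  for (i in 1:60) {
    kb <- random_kb(sample(2:6, 1), sample(2:6, 1))
    panel <- random_panel(kb)
    cfg <- ranker_config(
      floor = sample(c(0.01, 0.05), 1),
      missing_policy = sample(c("impute", "skip"), 1),
      top_k = sample(1:10, 1),
      score_mode = sample(c("posterior", "concordance"), 1))
    got <- tryCatch(
      suppressMessages(rank_diagnoses(kb, panel, cfg)),
      ihcdiff_empty_differential_error = function(e) NULL)
    want <- oracle_rank(kb, panel, cfg)
    if (is.null(got)) {
      expect_null(want)
      next
    }
    expect_identical(nrow(got), nrow(want))
    cfg_full <- cfg
    cfg_full$top_k <- nrow(kb$diseases)
    full <- oracle_rank(kb, panel, cfg_full)
    # per-disease score agreement against the untruncated oracle
    j <- match(got$disease_id, full$disease_id)
    expect_false(anyNA(j))
    expect_equal(exp(got$log_likelihood), full$likelihood[j], tolerance = 1e-9)
    expect_equal(got$posterior, full$posterior[j], tolerance = 1e-9)
    expect_equal(got$concordance, full$concordance[j], tolerance = 1e-9)
    expect_identical(got$n_profiled, as.integer(full$n_profiled[j]))
    # order agreement up to 1e-9 score ties: the package's ranking must be a
    # non-increasing walk through the oracle's scores
    oracle_score <- if (cfg$score_mode == "posterior") {
      stats::setNames(full$posterior, full$disease_id)
    } else {
      stats::setNames(full$concordance, full$disease_id)
    }
    s <- oracle_score[got$disease_id]
    if (length(s) > 1) expect_true(all(diff(s) <= 1e-9))
    left_out <- setdiff(full$disease_id, got$disease_id)
    if (length(left_out) && nrow(got)) {
      expect_lte(max(oracle_score[left_out]), min(s) + 1e-9)
    }
  }
})

test_that("panel insertion order never changes scores or ranks", {
  set.seed(402)
  for (i in 1:20) {
    kb <- random_kb(5, 6)
    panel <- random_panel(kb, size = 5)
    perm <- sample(length(panel))
    shuffled <- structure(unclass(panel)[perm], class = "case_panel")
    a <- rank_diagnoses(kb, panel)
    b <- rank_diagnoses(kb, shuffled)
    expect_identical(a$disease_id, b$disease_id)
    expect_equal(a$posterior, b$posterior, tolerance = 1e-12)
  }
})

test_that("a marker with identical positivity everywhere changes nothing", {
  kb <- tiny_kb()
  base <- rank_diagnoses(kb, case_panel(c(A = "+", B = "-")))
  kb2 <- kb
  kb2$antibodies <- antibody_registry(c("A", "B", "C", "Z"))
  kb2$profiles <- rbind(kb$profiles,
                        data.frame(disease_id = c("D1", "D2", "D3"),
                                   antibody = "Z", value = 0.6))
  with_z <- rank_diagnoses(kb2, case_panel(c(A = "+", B = "-", Z = "+")))
  expect_identical(with_z$disease_id, base$disease_id)
  expect_equal(with_z$posterior[match(base$disease_id, with_z$disease_id)],
               base$posterior, tolerance = 1e-9)
  # every likelihood scaled by the same factor (0.6)
  expect_equal(exp(with_z$log_likelihood - base$log_likelihood[
    match(with_z$disease_id, base$disease_id)]),
    rep(0.6, 3), tolerance = 1e-9)
})

test_that("raising a positively-observed positivity never lowers the posterior", {
  set.seed(403)
  for (i in 1:15) {
    kb <- random_kb(4, 5, density = 1)
    panel <- random_panel(kb, size = 4)
    pos_markers <- names(panel)[as.vector(panel)]
    if (!length(pos_markers)) next
    a <- pos_markers[1]
    d <- sample(kb$diseases$disease_id, 1)
    idx <- which(kb$profiles$disease_id == d & kb$profiles$antibody == a)
    before <- rank_diagnoses(kb, panel, ranker_config(top_k = 99))
    kb$profiles$value[idx] <- min(1, kb$profiles$value[idx] + 0.2)
    after <- rank_diagnoses(kb, panel, ranker_config(top_k = 99))
    expect_gte(after$posterior[after$disease_id == d] + 1e-12,
               before$posterior[before$disease_id == d])
  }
})

test_that("factors are floored away from 0 and 1 and likelihoods stay finite", {
  kb <- tiny_kb()
  kb$profiles$value <- c(0, 1, 0, 1, 0, 1, 0, 1, 0)
  res <- rank_diagnoses(kb, case_panel(c(A = "+", B = "-", C = "+")))
  facs <- unlist(attr(res, "factors"))
  expect_true(all(facs > 0 & facs < 1))
  expect_true(all(is.finite(res$log_likelihood)))
})

test_that("uniform-prior posteriors ignore common likelihood rescaling", {
  ll <- c(a = -3, b = -1, c = -2)
  expect_equal(normalize_posteriors(ll), normalize_posteriors(ll - 57.3),
               tolerance = 1e-12)
})

test_that("ranker configuration is validated", {
  expect_error(ranker_config(floor = 0), class = "ihcdiff_argument_error")
  expect_error(ranker_config(floor = 0.6), class = "ihcdiff_argument_error")
  expect_error(ranker_config(impute_value = 2), class = "ihcdiff_range_error")
  expect_error(ranker_config(top_k = 0), class = "ihcdiff_argument_error")
  expect_error(ranker_config(prior = c(a = 0.5, b = 0.6)),
               class = "ihcdiff_argument_error")
  expect_error(case_panel(c(1, 0)), class = "ihcdiff_argument_error")
  expect_error(case_panel(c(A = "equivocal")),
               class = "ihcdiff_inconclusive_error")
})
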