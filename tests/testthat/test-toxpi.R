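test_that("potency transform maps micromolar AC50s to negative log molar", {
  expect_equal(neglog_molar(1), 6)
  expect_equal(neglog_molar(0.1), 7)
  expect_equal(neglog_molar(1e6), 0)  # 1 M
  expect_error(neglog_molar(0), "positive")
  expect_error(neglog_molar(-2), "positive")
})

test_that("input values combine potency and specificity with the burst filter", {
  expect_equal(input_value("active", 1, 5.4), 11.4)
  expect_equal(input_value("active", 0.1, 3), 10)
  expect_equal(input_value("active", 1, 2), 0)      # z = 2 is excluded
  expect_equal(input_value("active", 1, 1.99), 0)
  expect_equal(input_value("inactive"), 0)
  expect_equal(input_value("single_conc_presumed_inactive"), 0)
  expect_equal(input_value("untested"), 0)
  # floored at zero for potencies weaker than 1 M
  expect_equal(input_value("active", 1e8, 2.1), 0.1)
  expect_equal(input_value("active", 1e9, 2.5), 0)
  expect_error(input_value("active", NA, 5), "finite")
})

test_that("the input matrix is zero except for specific actives", {
  res <- make_results(list("C1", "A1", "active", 1, 5.4),
                      list("C1", "A2", "inactive"),
                      list("C2", "A1", "active", 1, 1.5),
                      list("C2", "A2", "inactive"))
  iv <- build_input_matrix(make_hts(res))
  expect_equal(iv["C1", "A1"], 11.4)
  expect_equal(sum(iv != 0), 1L)
  expect_true(all(iv >= 0))
})

test_that("slice raw sums pool input values over slice assays", {
  iv <- matrix(c(11.4, 0, 0, 2), 1, 4,
               dimnames = list("C1", c("A1", "A2", "A3", "A4")))
  iv <- rbind(iv, C2 = 0)
  m <- process_model("toy", list(s1 = c("A1", "A2"), s2 = "A3",
                                 s3 = c("A4", "MISSING_1")))
  rs <- slice_raw_sums(iv, m)
  expect_equal(rs["C1", ], c(s1 = 11.4, s2 = 0, s3 = 2))
  expect_equal(rs["C2", ], c(s1 = 0, s2 = 0, s3 = 0))
})

test_that("range normalization gives the slice-wise maximum chemical a score of 1", {
  # 5 chemicals x 3 equal slices; C1 strictly maximal everywhere
  iv <- matrix(c(10, 8, 12,
                 3, 0, 5,
                 0, 2, 1,
                 7, 1, 0,
                 0, 0, 0), 5, 3, byrow = TRUE,
               dimnames = list(sprintf("C%d", 1:5), c("A1", "A2", "A3")))
  m <- process_model("toy", list(s1 = "A1", s2 = "A2", s3 = "A3"))
  res <- toxpi_scores(iv, m)
  expect_equal(res$overall_score[res$chemical_id == "C1"], 1)
  expect_equal(res$rank[res$chemical_id == "C1"], 1L)
  expect_true(all(res$overall_score >= 0 & res$overall_score <= 1))

  # two chemicals, each maximal in one of two equal slices -> both 0.5
  iv2 <- matrix(c(10, 0, 0, 10), 2, 2,
                dimnames = list(c("A", "B"), c("A1", "A2")))
  m2 <- process_model("toy2", list(s1 = "A1", s2 = "A2"))
  res2 <- toxpi_scores(iv2, m2)
  expect_equal(res2$overall_score, c(0.5, 0.5))

  # degenerate slices (all chemicals tie) carry no information
  iv3 <- matrix(5, 3, 2, dimnames = list(c("A", "B", "C"), c("A1", "A2")))
  res3 <- toxpi_scores(iv3, m2)
  expect_equal(res3$overall_score, c(0, 0, 0))

  expect_error(toxpi_scores(iv3[1, , drop = FALSE], m2), ">= 2 chemicals")
})

test_that("scores conserve components, respect bounds, and shift-invariance", {
  set.seed(21)
  for (rep in 1:10) {
    x <- random_hts(6, 8)
    iv <- build_input_matrix(x)
    model <- random_model(colnames(iv), 4)
    res <- toxpi_scores(iv, model)
    comp <- as.matrix(res[, names(model$slices)])
    expect_equal(rowSums(comp), res$overall_score, tolerance = 1e-12)
    for (j in seq_along(model$slices))
      expect_true(all(comp[, j] >= 0 & comp[, j] <= model$weights[j] + 1e-12))

    # adding a constant to all raw sums of a slice leaves components unchanged
    iv_shift <- iv
    a1 <- model$slices[[1]][1]
    iv_shift[, a1] <- iv_shift[, a1] + 3.7
    res_shift <- toxpi_scores(iv_shift, model)
    expect_equal(res_shift[, names(model$slices)],
                 res[, names(model$slices)], tolerance = 1e-12)
  }
})

test_that("raising one input value never hurts the chemical itself", {
  set.seed(33)
  for (rep in 1:10) {
    x <- random_hts(5, 6, p_untested = 0.1)
    iv <- build_input_matrix(x)
    model <- random_model(colnames(iv), 3)
    base <- toxpi_scores(iv, model)
    i <- sample(nrow(iv), 1); j <- sample(ncol(iv), 1)
    iv2 <- iv
    iv2[i, j] <- iv2[i, j] + runif(1, 0.5, 5)
    bumped <- toxpi_scores(iv2, model)
    ci <- rownames(iv)[i]
    get <- function(r, id) r$overall_score[r$chemical_id == id]
    expect_gte(get(bumped, ci) - get(base, ci), -1e-12)
    # other chemicals can lose at most the affected slice's weight
    w_aff <- max(model$weights[vapply(model$slices, function(a)
      colnames(iv)[j] %in% a, TRUE)], 0)
    for (other in setdiff(rownames(iv), ci))
      expect_lte(get(base, other) - get(bumped, other), w_aff + 1e-12)
  }
})

test_that("scores match an independent straight-line oracle", {
  set.seed(99)
  for (rep in 1:25) {
    x <- random_hts(6, 8)
    iv <- build_input_matrix(x)
    model <- random_model(colnames(iv), sample(2:5, 1))
    res <- toxpi_scores(iv, model)
    expected <- oracle_toxpi(iv, model$slices, model$weights)
    expect_equal(res$overall_score[match(names(expected), res$chemical_id)],
                 unname(expected), tolerance = 1e-12)
  }
})

# local helper mirroring the package's competition ranking for fixtures
rank_scores_for_test <- function(score) {
  rk <- rep(NA_integer_, length(score))
  rk[score > 0] <- as.integer(rank(-score[score > 0], ties.method = "min"))
  rk
}

test_that("percentile bands follow the rank thresholds and the zero rule", {
  mk <- function(n, ranks = seq_len(n), scores = NULL) {
    if (is.null(scores)) scores <- rev(seq_len(n)) / n
    data.frame(chemical_id = sprintf("C%04d", seq_len(n)),
               overall_score = scores, rank = ranks)
  }
  r <- rank_and_band(mk(1000), "active_only")
  expect_equal(as.character(r$band[r$rank == 50]), "top5")   # boundary inclusive
  expect_equal(as.character(r$band[r$rank == 51]), "top10")
  expect_equal(as.character(r$band[r$rank == 100]), "top10")
  expect_equal(as.character(r$band[r$rank == 150]), "top15")
  expect_equal(as.character(r$band[r$rank == 151]), "none")

  r200 <- rank_and_band(mk(200), "active_only")
  expect_equal(as.character(r200$band[r200$rank == 25]), "top15")  # 0.125

  # score 0 -> not_active regardless of denominator
  d <- mk(10)
  d$overall_score[10] <- 0
  d$rank[10] <- NA
  for (pol in c("active_only", "full_library"))
    expect_equal(as.character(rank_and_band(d, pol)$band[10]), "not_active")

  # policies differ when many chemicals score 0
  d2 <- mk(100)
  d2$overall_score[21:100] <- 0
  d2$rank <- rank_scores_for_test(d2$overall_score)
  ao <- rank_and_band(d2, "active_only")
  fl <- rank_and_band(d2, "full_library")
  expect_equal(as.character(ao$band[ao$rank %in% 1]), "top5")
  expect_equal(as.character(fl$band[fl$rank %in% 5]), "top5")
  expect_equal(as.character(ao$band[ao$rank %in% 5]), "none")  # 5/20 = 0.25
})

test_that("prioritization flags top ~10% chemicals in any model", {
  mk <- function(bands) data.frame(
    chemical_id = sprintf("C%d", seq_along(bands)),
    overall_score = ifelse(bands == "not_active", 0, 0.5),
    rank = seq_along(bands),
    band = factor(bands, levels = c("top5", "top10", "top15", "none", "not_active")))
  m1 <- mk(c("top5", "top15", "none"))
  m2 <- mk(c("none", "top15", "not_active"))
  expect_equal(prioritize(list(a = m1, b = m2)), "C1")
  expect_error(prioritize(list()), "no models")
})

test_that("RAR companion score is the single-slice normalization", {
  res <- make_results(list("C1", "RARA_1", "active", 0.1, 6),
                      list("C2", "RARA_1", "active", 10, 4),
                      list("C3", "RARA_1", "inactive"))
  x <- make_hts(res, assay_ids = c("RARA_1", "RARB_1", "RARG_1"))
  iv <- build_input_matrix(x)
  rs <- rar_scores(iv)
  expect_equal(rs$rar_score[rs$chemical_id == "C1"], 1)
  expect_equal(rs$rar_score[rs$chemical_id == "C3"], 0)
  # order-isomorphic to the raw slice sums
  raw <- slice_raw_sums(iv, rar_model())[, 1]
  expect_equal(order(-rs$rar_score), order(-raw))
})
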