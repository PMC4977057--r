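test_that("z-score binning hits the published category boundaries", {
  expect_equal(bin_z("active", 5), 2L)
  expect_equal(bin_z("active", 9.5), 4L)
  expect_equal(bin_z("active", 3), 1L)     # boundary inclusive
  expect_equal(bin_z("active", 6), 2L)
  expect_equal(bin_z("active", 9), 3L)
  expect_equal(bin_z("active", -1), 1L)
  expect_equal(bin_z("inactive"), 0L)
  expect_equal(bin_z("single_conc_presumed_inactive"), 0L)
  expect_true(is.na(bin_z("untested")))
})

test_that("binned matrix encodes untested as NA and honours the coverage filter", {
  res <- make_results(list("C1", "A1", "active", 1, 5),
                      list("C1", "A2", "inactive"),
                      list("C2", "A1", "active", 1, 10))
  x <- make_hts(res)
  b <- build_binned_matrix(x)
  expect_equal(b["C1", ], c(A1 = 2L, A2 = 0L))
  expect_equal(b["C2", "A1"], 4L)
  expect_true(is.na(b["C2", "A2"]))

  b_all <- build_binned_matrix(x, coverage_filter = 0)
  expect_equal(nrow(b_all), 2L)
  b_dense <- build_binned_matrix(x, coverage_filter = 0.8)
  expect_equal(rownames(b_dense), "C1")
  expect_error(build_binned_matrix(x, coverage_filter = 1.1),
               "removes every chemical")

  # two-tier synthetic coverage: a 0.8 floor keeps exactly the dense tier
  ds <- simulate_scenario("null", seed = 9)
  bt <- build_binned_matrix(ds$matrix, coverage_filter = 0.8)
  expect_setequal(rownames(bt),
                  ds$truth$chemical_id[ds$truth$tier == "dense"])
  expect_false(anyNA(bt))  # dense tier is fully tested
})

test_that("pairwise Pearson handles perfect, inverse, and undefined cases", {
  m <- rbind(C1 = c(0, 1, 2, 3, 4),
             C2 = c(0, 1, 2, 3, 4),
             C3 = c(4, 3, 2, 1, 0),
             C4 = c(2, 2, 2, 2, 2))
  colnames(m) <- sprintf("A%d", 1:5)
  e <- pairwise_pearson(m, min_overlap = 2)
  g <- function(a, b) e$pearson_r[e$chem_a == a & e$chem_b == b]
  expect_equal(g("C1", "C2"), 1)
  expect_equal(g("C1", "C3"), -1)
  expect_true(is.na(g("C1", "C4")))  # constant vector: r undefined
  expect_true(all(e$pearson_r >= -1 & e$pearson_r <= 1, na.rm = TRUE))
  expect_error(pairwise_pearson(m, min_overlap = 1), ">= 2")
})

test_that("pairwise Pearson matches a brute-force per-pair oracle", {
  set.seed(14)
  for (rep in 1:20) {
    m <- matrix(sample(c(NA, 0:4), 50, replace = TRUE,
                       prob = c(0.25, 0.35, 0.1, 0.1, 0.1, 0.1)),
                5, 10, dimnames = list(sprintf("C%d", 1:5), sprintf("A%d", 1:10)))
    got <- pairwise_pearson(m, min_overlap = 3)
    want <- oracle_pearson(m, min_overlap = 3)
    expect_equal(got$pearson_r, want$pearson_r, tolerance = 1e-12)
    expect_equal(got$n_overlap, want$n_overlap)
  }
})

test_that("assays untested in both chemicals do not change r", {
  set.seed(8)
  m <- matrix(sample(0:4, 40, replace = TRUE), 4, 10,
              dimnames = list(sprintf("C%d", 1:4), sprintf("A%d", 1:10)))
  base <- pairwise_pearson(m, min_overlap = 2)
  m2 <- cbind(m, A11 = NA_integer_)
  extended <- pairwise_pearson(m2, min_overlap = 2)
  expect_equal(extended$pearson_r, base$pearson_r)
})

test_that("top_similar ranks a planted near-duplicate first", {
  set.seed(4)
  m <- matrix(sample(0:4, 12 * 20, replace = TRUE), 12, 20,
              dimnames = list(sprintf("C%02d", 1:12), sprintf("A%d", 1:20)))
  dup <- m["C01", ]
  dup[1] <- (dup[1] + 1L) %% 5L  # perturb one entry
  m <- rbind(m, DUP = dup)
  e <- pairwise_pearson(m, min_overlap = 10)
  top <- top_similar(e, "C01", k = 5)
  expect_equal(top$chemical_id[1], "DUP")
  expect_equal(top$rank, 1:5)

  # k larger than the candidate pool returns everything defined
  top_all <- top_similar(e, "C01", k = 100)
  expect_lte(nrow(top_all), 12)

  # exclusion predicate removes tagged candidates
  top_ex <- top_similar(e, "C01", k = 5,
                        exclude = function(id) id == "DUP")
  expect_false("DUP" %in% top_ex$chemical_id)
  top_ex2 <- top_similar(e, "C01", k = 5, exclude = "DUP")
  expect_equal(top_ex$chemical_id, top_ex2$chemical_id)

  expect_error(top_similar(e, "NOPE"), "unknown chemical")
})

test_that("AC50-based similarity can reorder neighbours that tie in bins", {
  # C2 and C3 have identical bins from the query's viewpoint, but C2's
  # potencies track the query's exactly while C3's are shuffled.
  mk_row <- function(id, ac50s, zs) {
    do.call(rbind, lapply(seq_along(ac50s), function(i)
      data.frame(chemical_id = id, assay_id = sprintf("A%d", i),
                 hit_call = "active", ac50_uM = ac50s[i], z_score = zs[i])))
  }
  zs <- rep(c(2, 5, 8, 10), 3)  # bins 1,2,3,4 repeated
  q_ac <- 10^seq(-2, 2, length.out = 12)
  res <- rbind(mk_row("Q", q_ac, zs),
               mk_row("C2", q_ac * 1.5, zs),
               mk_row("C3", rev(q_ac), zs))
  x <- make_hts(res)

  eb <- pairwise_pearson(build_binned_matrix(x), min_overlap = 10)
  ea <- pairwise_pearson_ac50(x, min_overlap = 10)
  gb <- function(e, b) e$pearson_r[(e$chem_a == "Q" & e$chem_b == b) |
                                   (e$chem_b == "Q" & e$chem_a == b)]
  expect_equal(gb(eb, "C2"), gb(eb, "C3"))        # bins tie
  expect_gt(gb(ea, "C2"), gb(ea, "C3"))           # potencies separate
  expect_equal(gb(ea, "C2"), 1)

  # all-inactive profiles are constant -> undefined
  res2 <- make_results(list("C1", "A1", "inactive"), list("C1", "A2", "inactive"),
                       list("C2", "A1", "inactive"), list("C2", "A2", "inactive"))
  e2 <- pairwise_pearson_ac50(make_hts(res2), min_overlap = 2)
  expect_true(is.na(e2$pearson_r))
})
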