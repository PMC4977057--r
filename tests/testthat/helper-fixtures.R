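# Shared fixtures and independent oracle implementations. The oracles are
# deliberately plain loops sharing no code with the package, so they can
# arbitrate the vectorized implementations.

# small long-format results builder
make_results <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(chemical_id = r[[1]], assay_id = r[[2]], hit_call = r[[3]],
               ac50_uM = if (length(r) > 3) as.numeric(r[[4]]) else NA_real_,
               z_score = if (length(r) > 4) as.numeric(r[[5]]) else NA_real_)))
}

make_hts <- function(results, chem_ids = NULL, assay_ids = NULL) {
  if (is.null(chem_ids)) chem_ids <- unique(results$chemical_id)
  if (is.null(assay_ids)) assay_ids <- unique(results$assay_id)
  hts_matrix(data.frame(chemical_id = chem_ids, name = chem_ids),
             assay_ids, results)
}

# straight-line ToxPi re-implementation: per-chemical loops, no shared code
oracle_toxpi <- function(iv, slices, weights) {
  n <- nrow(iv)
  raw <- matrix(0, n, length(slices))
  for (i in seq_len(n))
    for (j in seq_along(slices))
      for (a in slices[[j]])
        if (a %in% colnames(iv)) raw[i, j] <- raw[i, j] + iv[i, a]
  comp <- matrix(0, n, length(slices))
  for (j in seq_along(slices)) {
    lo <- min(raw[, j]); hi <- max(raw[, j])
    if (hi > lo)
      for (i in seq_len(n)) comp[i, j] <- (raw[i, j] - lo) / (hi - lo) * weights[j]
  }
  overall <- numeric(n)
  for (i in seq_len(n)) overall[i] <- sum(comp[i, ])
  names(overall) <- rownames(iv)
  overall
}

# naive per-pair pairwise-complete Pearson
oracle_pearson <- function(m, min_overlap) {
  ids <- rownames(m)
  out <- NULL
  for (i in seq_len(nrow(m) - 1)) {
    for (j in seq((i + 1), nrow(m))) {
      x <- m[i, ]; y <- m[j, ]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      r <- NA_real_
      if (length(x) >= min_overlap) {
        sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
        if (sx > 0 && sy > 0)
          r <- sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
      }
      out <- rbind(out, data.frame(chem_a = ids[i], chem_b = ids[j],
                                   pearson_r = r, n_overlap = length(x)))
    }
  }
  out[order(out$chem_a, out$chem_b), ]
}

# random small hts_matrix for property checks
random_hts <- function(n_chem = 6, n_assay = 8, p_untested = 0.2,
                       p_inactive = 0.4) {
  chem <- sprintf("C%02d", seq_len(n_chem))
  assay <- sprintf("A%02d", seq_len(n_assay))
  rows <- NULL
  for (ci in chem) for (ai in assay) {
    u <- runif(1)
    if (u < p_untested) next
    if (u < p_untested + p_inactive) {
      rows <- rbind(rows, data.frame(chemical_id = ci, assay_id = ai,
                                     hit_call = "inactive",
                                     ac50_uM = NA_real_, z_score = NA_real_))
    } else {
      rows <- rbind(rows, data.frame(chemical_id = ci, assay_id = ai,
                                     hit_call = "active",
                                     ac50_uM = 10^runif(1, -2, 2),
                                     z_score = runif(1, 0, 12)))
    }
  }
  hts_matrix(data.frame(chemical_id = chem, name = chem), assay, rows)
}

random_model <- function(assay_ids, n_slices = 3) {
  grp <- split(assay_ids, sort(rep_len(seq_len(n_slices), length(assay_ids))))
  names(grp) <- sprintf("S%d", seq_len(n_slices))
  process_model("random_model", grp)
}
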