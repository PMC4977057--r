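# Chemical-chemical similarity over binned bioactivity fingerprints.
#
# Unlike the ToxPi transform, the binning keeps weakly specific actives
# (z <= 3 maps to category 1, not 0): the two stages of the analysis apply
# different specificity handling by design.

#' Bin z-scores into the six similarity categories
#'
#' Untested -> `NA`; tested inactive (or single-concentration presumed
#' inactive) -> 0; active with z <= 3 -> 1; 3 < z <= 6 -> 2; 6 < z <= 9 -> 3;
#' z > 9 -> 4. The last four categories indicate increasing specificity of
#' the bioactivity.
#'
#' @param hit_call character vector of hit calls.
#' @param z_score z-scores (required where active).
#' @return integer vector with values in `{NA, 0, 1, 2, 3, 4}`.
#' @export
bin_z <- function(hit_call, z_score = NA_real_) {
  n <- length(hit_call)
  z <- rep_len(as.numeric(z_score), n)
  bad <- setdiff(unique(hit_call), HIT_CALLS)
  if (length(bad))
    stop("unknown hit_call value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- rep(NA_integer_, n)
  out[hit_call %in% c("inactive", "single_conc_presumed_inactive")] <- 0L
  act <- hit_call == "active"
  if (any(act & !is.finite(z)))
    stop("active pairs need a finite z_score", call. = FALSE)
  out[act] <- cut(z[act], c(-Inf, 3, 6, 9, Inf), labels = FALSE)
  out
}

#' Build the binned fingerprint matrix
#'
#' Optionally drops chemicals below a testing-coverage floor first (the
#' correlation analysis is restricted to the densely tested subset of the
#' library to limit the impact of missing data), then applies [bin_z()]
#' elementwise. Untested pairs are `NA`.
#'
#' @param x an [hts_matrix()].
#' @param coverage_filter optional minimum per-chemical fraction tested in
#'   `[0, 1]`; `NULL` keeps every chemical.
#' @return integer matrix (chemicals x assays) with entries in
#'   `{NA, 0, 1, 2, 3, 4}`.
#' @export
build_binned_matrix <- function(x, coverage_filter = NULL) {
  stopifnot(inherits(x, "hts_matrix"))
  if (!is.null(coverage_filter)) {
    cov <- coverage_stats(x)$by_chemical
    keep <- cov$chemical_id[cov$fraction_tested >= coverage_filter]
    if (!length(keep))
      stop("coverage filter ", coverage_filter, " removes every chemical",
           call. = FALSE)
    x <- subset_hts(x, chemicals = keep)
  }
  m <- matrix(NA_integer_, nrow(x$chemicals), nrow(x$assays),
              dimnames = list(x$chemicals$chemical_id, x$assays$assay_id))
  r <- x$results
  if (nrow(r))
    m[cbind(match(r$chemical_id, rownames(m)),
            match(r$assay_id, colnames(m)))] <- bin_z(r$hit_call, r$z_score)
  m
}

# Pairwise-complete Pearson over the rows of `m`, as a long table of
# unordered pairs. r is NA (undefined) when the overlap is below
# `min_overlap` or either restricted vector is constant.
pairwise_cor_long <- function(m, min_overlap) {
  if (min_overlap < 2) stop("min_overlap must be >= 2", call. = FALSE)
  if (nrow(m) < 2) stop("need at least two chemicals", call. = FALSE)
  r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  n_ov <- crossprod(!is.na(t(m)))
  r[n_ov < min_overlap] <- NA_real_
  idx <- which(upper.tri(r), arr.ind = TRUE)
  ids <- rownames(m)
  out <- data.frame(chem_a = ids[idx[, 1]], chem_b = ids[idx[, 2]],
                    pearson_r = r[idx], n_overlap = as.integer(n_ov[idx]),
                    row.names = NULL)
  out[order(out$chem_a, out$chem_b), , drop = FALSE]
}

#' Pairwise-complete Pearson similarity of binned fingerprints
#'
#' For each unordered chemical pair, restricts the two binned fingerprints
#' to the assays tested in both and computes Pearson's r there. Pairs whose
#' overlap is below `min_overlap`, or where either restricted vector is
#' constant (Pearson r undefined), get `NA`.
#'
#' @param binned matrix from [build_binned_matrix()].
#' @param min_overlap minimum number of jointly tested assays (>= 2);
#'   r on tiny overlaps is noise, so the default floor is 10.
#' @return data.frame `chem_a`, `chem_b`, `pearson_r`, `n_overlap`, one row
#'   per unordered pair.
#' @export
pairwise_pearson <- function(binned, min_overlap = 10) {
  stopifnot(is.matrix(binned))
  pairwise_cor_long(binned, min_overlap)
}

#' Pairwise Pearson similarity of potency profiles
#'
#' Alternate similarity on AC50-based vectors: active pairs contribute
#' `neglog_molar(ac50)`, tested-inactive pairs 0, untested pairs `NA`.
#' Compared with the binned z-score profile this emphasizes potency over
#' specificity, so the two rankings can disagree.
#'
#' @param x an [hts_matrix()].
#' @param min_overlap as in [pairwise_pearson()].
#' @param coverage_filter optional per-chemical coverage floor, as in
#'   [build_binned_matrix()].
#' @return data.frame as in [pairwise_pearson()].
#' @export
pairwise_pearson_ac50 <- function(x, min_overlap = 10, coverage_filter = NULL) {
  stopifnot(inherits(x, "hts_matrix"))
  if (!is.null(coverage_filter)) {
    cov <- coverage_stats(x)$by_chemical
    keep <- cov$chemical_id[cov$fraction_tested >= coverage_filter]
    if (!length(keep))
      stop("coverage filter removes every chemical", call. = FALSE)
    x <- subset_hts(x, chemicals = keep)
  }
  m <- matrix(NA_real_, nrow(x$chemicals), nrow(x$assays),
              dimnames = list(x$chemicals$chemical_id, x$assays$assay_id))
  r <- x$results
  if (nrow(r)) {
    v <- numeric(nrow(r))
    act <- r$hit_call == "active"
    v[act] <- neglog_molar(r$ac50_uM[act])
    m[cbind(match(r$chemical_id, rownames(m)),
            match(r$assay_id, colnames(m)))] <- v
  }
  pairwise_cor_long(m, min_overlap)
}

#' Most similar chemicals to a query
#'
#' Ranks the query's similarity entries by Pearson r (descending; ties
#' broken by candidate id), dropping undefined correlations. An optional
#' exclusion filters candidates, e.g. to list the most similar
#' nonpharmaceuticals.
#'
#' @param entries data.frame from [pairwise_pearson()] or
#'   [pairwise_pearson_ac50()].
#' @param chemical_id the query chemical.
#' @param k number of neighbours to return (fewer if fewer candidates).
#' @param exclude either a character vector of candidate ids to drop, or a
#'   predicate `function(id) TRUE/FALSE` returning TRUE for candidates to
#'   drop.
#' @return data.frame `rank`, `chemical_id`, `pearson_r`, `n_overlap`.
#' @export
top_similar <- function(entries, chemical_id, k = 10, exclude = NULL) {
  stopifnot(all(c("chem_a", "chem_b", "pearson_r", "n_overlap") %in% names(entries)))
  hit <- entries$chem_a == chemical_id | entries$chem_b == chemical_id
  if (!any(hit) &&
      !chemical_id %in% c(entries$chem_a, entries$chem_b))
    stop("unknown chemical: ", chemical_id, call. = FALSE)
  e <- entries[hit, , drop = FALSE]
  other <- ifelse(e$chem_a == chemical_id, e$chem_b, e$chem_a)
  keep <- !is.na(e$pearson_r)
  if (!is.null(exclude)) {
    drop <- if (is.function(exclude)) vapply(other, exclude, TRUE)
            else other %in% exclude
    keep <- keep & !drop
  }
  e <- e[keep, , drop = FALSE]; other <- other[keep]
  ord <- order(-e$pearson_r, other)
  take <- utils::head(ord, k)
  data.frame(rank = seq_along(take), chemical_id = other[take],
             pearson_r = e$pearson_r[take], n_overlap = e$n_overlap[take],
             row.names = NULL)
}
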