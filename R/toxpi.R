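# ToxPi scoring core.
#
# The per-pair input value combines potency and specificity: the AC50 is
# converted to negative log molar units (1 uM -> 6) and the cytotoxicity-
# distance z-score is added, so more potent and more cytotoxicity-specific
# hits contribute more. Pairs that are inactive, untested, or have z <= 2
# (likely cytotoxic-burst artifacts) contribute 0.

#' Convert an AC50 in micromolar to negative log molar units
#'
#' `-log10(ac50_uM * 1e-6)`; an AC50 of 1 uM maps to 6, 0.1 uM to 7.
#'
#' @param ac50_uM positive AC50 value(s) in micromolar.
#' @return numeric vector of negative log molar potencies.
#' @export
neglog_molar <- function(ac50_uM) {
  ac50_uM <- as.numeric(ac50_uM)
  if (any(!is.finite(ac50_uM)) || any(ac50_uM <= 0))
    stop("ac50_uM must be positive and finite", call. = FALSE)
  6 - log10(ac50_uM)
}

#' ToxPi input value for chemical-assay pairs
#'
#' Active pairs with z-score > 2 score `neglog_molar(ac50) + z` (floored at
#' 0); active pairs with z <= 2 are treated as cytotoxic-burst artifacts and
#' score 0, as do inactive, presumed-inactive, and untested pairs.
#'
#' @param hit_call character vector of hit calls (see [hts_matrix()]).
#' @param ac50_uM AC50s in micromolar (required where active).
#' @param z_score cytotoxicity-distance z-scores (required where active).
#' @return nonnegative numeric vector of input values.
#' @export
input_value <- function(hit_call, ac50_uM = NA_real_, z_score = NA_real_) {
  n <- length(hit_call)
  ac50_uM <- rep_len(as.numeric(ac50_uM), n)
  z_score <- rep_len(as.numeric(z_score), n)
  bad <- setdiff(unique(hit_call), HIT_CALLS)
  if (length(bad))
    stop("unknown hit_call value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out <- numeric(n)
  act <- hit_call == "active"
  if (any(act & (!is.finite(ac50_uM) | !is.finite(z_score))))
    stop("active pairs need finite ac50_uM and z_score", call. = FALSE)
  keep <- act & z_score > 2
  out[keep] <- pmax(0, neglog_molar(ac50_uM[keep]) + z_score[keep])
  out
}

#' Build the chemical-by-assay input-value matrix
#'
#' Applies [input_value()] to every stored result; pairs with no stored
#' result (untested) score 0 under the scoring policy (missing data is no
#' evidence of activity).
#'
#' @param x an [hts_matrix()].
#' @return numeric matrix (chemicals x assays) of nonnegative input values,
#'   with chemical ids as row names and assay ids as column names.
#' @export
build_input_matrix <- function(x) {
  stopifnot(inherits(x, "hts_matrix"))
  iv <- matrix(0, nrow(x$chemicals), nrow(x$assays),
               dimnames = list(x$chemicals$chemical_id, x$assays$assay_id))
  r <- x$results
  if (nrow(r))
    iv[cbind(match(r$chemical_id, rownames(iv)),
             match(r$assay_id, colnames(iv)))] <-
      input_value(r$hit_call, r$ac50_uM, r$z_score)
  iv
}

#' Per-chemical raw slice sums under a model
#'
#' Sums input values across the assays of each slice. Model assays absent
#' from the matrix contribute 0 (sparse panels are legal).
#'
#' @param iv input-value matrix from [build_input_matrix()].
#' @param model a [process_model()].
#' @return numeric matrix (chemicals x slices) of raw sums.
#' @export
slice_raw_sums <- function(iv, model) {
  stopifnot(is.matrix(iv), inherits(model, "process_model"))
  out <- vapply(model$slices, function(a) {
    a <- intersect(a, colnames(iv))
    if (!length(a)) return(numeric(nrow(iv)))
    rowSums(iv[, a, drop = FALSE])
  }, numeric(nrow(iv)))
  if (nrow(iv) == 1L) out <- matrix(out, 1, dimnames = list(rownames(iv), names(model$slices)))
  rownames(out) <- rownames(iv)
  out
}

#' ToxPi scores for a model
#'
#' Each slice's raw sums are range-normalized across chemicals to 0-1
#' (subtract the minimum, divide by the range; a degenerate slice where all
#' chemicals tie scores 0 for everyone), multiplied by the slice weight to
#' give the component score, and the components are summed to the overall
#' score in `[0, 1]`. A score of 1 means the chemical attains the maximum
#' raw sum in every slice. Ranks are competition ("min") ranks over
#' chemicals with a positive score; score-0 chemicals get rank `NA`.
#'
#' @param iv input-value matrix from [build_input_matrix()] (>= 2 chemicals:
#'   normalization is population-relative).
#' @param model a [process_model()].
#' @return data.frame, sorted by decreasing overall score (ties broken by
#'   chemical id): `chemical_id`, `overall_score`, `rank`, then one
#'   component-score column per slice.
#' @export
toxpi_scores <- function(iv, model) {
  if (nrow(iv) < 2)
    stop("toxpi_scores needs >= 2 chemicals: slice normalization is ",
         "relative to the scored population", call. = FALSE)
  raw <- slice_raw_sums(iv, model)
  comp <- raw
  for (j in seq_len(ncol(raw))) {
    rng <- range(raw[, j])
    comp[, j] <- if (rng[2] > rng[1])
      (raw[, j] - rng[1]) / (rng[2] - rng[1]) * model$weights[j]
    else 0
  }
  overall <- rowSums(comp)
  rk <- rank_scores(overall)
  out <- data.frame(chemical_id = rownames(iv), overall_score = overall,
                    rank = rk, row.names = NULL)
  out <- cbind(out, as.data.frame(comp, row.names = NULL))
  out <- out[order(-out$overall_score, out$chemical_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "model_name") <- model$model_name
  attr(out, "slice_names") <- names(model$slices)
  out
}

# competition ranks over positive scores; NA where score == 0
rank_scores <- function(score) {
  rk <- rep(NA_integer_, length(score))
  pos <- score > 0
  rk[pos] <- as.integer(rank(-score[pos], ties.method = "min"))
  rk
}

#' Assign percentile bands to ToxPi results
#'
#' Chemicals with score 0 are `not_active` and excluded from banding.
#' Among scored chemicals, band thresholds are on `rank / N`: `top5` if
#' <= 0.05, `top10` if <= 0.10, `top15` if <= 0.15, else `none`. The
#' denominator N is the count of chemicals with positive score
#' (`active_only`, the default) or all chemicals (`full_library`).
#'
#' @param results data.frame from [toxpi_scores()].
#' @param denominator_policy `"active_only"` or `"full_library"`.
#' @return `results` with a `band` factor column added.
#' @export
rank_and_band <- function(results,
                          denominator_policy = c("active_only", "full_library")) {
  denominator_policy <- match.arg(denominator_policy)
  stopifnot(all(c("chemical_id", "overall_score", "rank") %in% names(results)))
  n <- if (denominator_policy == "active_only")
    sum(results$overall_score > 0) else nrow(results)
  frac <- results$rank / max(1L, n)
  band <- rep("not_active", nrow(results))
  scored <- results$overall_score > 0
  band[scored] <- ifelse(frac[scored] <= 0.05, "top5",
                  ifelse(frac[scored] <= 0.10, "top10",
                  ifelse(frac[scored] <= 0.15, "top15", "none")))
  results$band <- factor(band, levels = c("top5", "top10", "top15", "none",
                                          "not_active"))
  attr(results, "denominator_policy") <- denominator_policy
  results
}

#' Flag chemicals of interest across models
#'
#' A chemical is flagged when it is in the top ~10% (band `top5` or `top10`)
#' in at least one biological process model.
#'
#' @param results_by_model named list of banded results from
#'   [rank_and_band()].
#' @return character vector of flagged chemical ids, sorted.
#' @export
prioritize <- function(results_by_model) {
  if (!length(results_by_model)) stop("no models scored", call. = FALSE)
  flagged <- unlist(lapply(results_by_model, function(r) {
    stopifnot("band" %in% names(r))
    r$chemical_id[r$band %in% c("top5", "top10")]
  }), use.names = FALSE)
  sort(unique(flagged))
}

#' RAR companion scores
#'
#' Scores the single-slice retinoic acid receptor model with the same
#' machinery as [toxpi_scores()]; reported alongside the adipocyte
#' differentiation results so RAR agonists can be discounted.
#'
#' @param iv input-value matrix from [build_input_matrix()].
#' @param model the RAR companion model (default [rar_model()]).
#' @return data.frame `chemical_id`, `rar_score`, in input-matrix order.
#' @export
rar_scores <- function(iv, model = rar_model()) {
  if (length(model$slices) != 1L)
    stop("the RAR companion model has a single slice", call. = FALSE)
  res <- toxpi_scores(iv, model)
  data.frame(chemical_id = rownames(iv),
             rar_score = res$overall_score[match(rownames(iv), res$chemical_id)],
             row.names = NULL)
}
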