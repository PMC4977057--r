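# End-to-end orchestration: score -> rank/band -> prioritize -> similarity
# -> cluster, with every table written as TSV under a single output
# directory and a JSON manifest recording the configuration, the seed, and
# a checksum per output so a run can be verified as reproduced.

tsv_header <- function(seed) {
  sprintf("# toxpiscreen %s seed=%s",
          as.character(utils::packageVersion("toxpiscreen")),
          format(seed))
}

write_tsv_report <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(seed), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Cross-model band matrix with star notation
#'
#' One row per chemical, one column per model, with cells `"***"` (top ~5th
#' percentile), `"**"` (top ~10th), `"*"` (top ~15th), `""` (scored, below
#' the bands), and `"-"` (not active, score = 0). Chemicals absent from a
#' model's results are shown as not active.
#'
#' @param results_by_model named list of banded results from
#'   [rank_and_band()].
#' @return data.frame `chemical_id` plus one star column per model.
#' @export
band_matrix <- function(results_by_model) {
  if (!length(results_by_model)) stop("no models selected", call. = FALSE)
  stars <- c(top5 = "***", top10 = "**", top15 = "*", none = "",
             not_active = "-")
  ids <- sort(unique(unlist(lapply(results_by_model, `[[`, "chemical_id"))))
  out <- data.frame(chemical_id = ids)
  for (m in names(results_by_model)) {
    r <- results_by_model[[m]]
    cell <- stars[as.character(r$band[match(ids, r$chemical_id)])]
    cell[is.na(cell)] <- "-"
    out[[m]] <- unname(cell)
  }
  out
}

#' Run the full prioritization analysis
#'
#' Executes the pipeline on an HTS matrix: ToxPi scoring of every model
#' (with the RAR companion score appended to the adipocyte differentiation
#' table when that model is present), percentile banding, top-10%
#' prioritization, binned z-score similarity with ranked neighbour lists
#' for the flagged chemicals, and PCA + k-means clustering of one model's
#' component-score profiles. All outputs are TSVs with a `#` header line
#' carrying the package version and seed, plus a JSON manifest with md5
#' checksums.
#'
#' @param x an [hts_matrix()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (drives the clustering initialization and is
#'   recorded in every output header).
#' @param models named list of [process_model()]s (default
#'   [bundled_models()]).
#' @param rar optional RAR companion model (default [rar_model()]; `NULL`
#'   to skip).
#' @param denominator_policy banding denominator, see [rank_and_band()].
#' @param coverage_filter per-chemical coverage floor for the similarity
#'   stage (default 0.8, keeping the densely tested tier).
#' @param min_overlap minimum pairwise overlap for Pearson r.
#' @param similarity_mode `"binned_z"` (default) or `"ac50"`.
#' @param cluster_model name of the model whose slice scores are clustered
#'   (default `"feeding_behavior_celegans"`; skipped if absent).
#' @param pca_threshold explained-variance retention threshold.
#' @param restarts k-means restarts.
#' @param top_k neighbours per query in the similarity tables.
#' @return list with `results_by_model`, `flagged`, `similarity`,
#'   `clustering`, `manifest` (paths and checksums), invisibly.
#' @export
run_full_analysis <- function(x, out_dir, seed,
                              models = bundled_models(),
                              rar = rar_model(),
                              denominator_policy = "active_only",
                              coverage_filter = 0.8, min_overlap = 10,
                              similarity_mode = c("binned_z", "ac50"),
                              cluster_model = "feeding_behavior_celegans",
                              pca_threshold = 0.05, restarts = 10,
                              top_k = 10) {
  stopifnot(inherits(x, "hts_matrix"))
  similarity_mode <- match.arg(similarity_mode)
  if (!length(models)) stop("no models selected", call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, `[[`, "", "model_name")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  files <- character()

  stage <- function(msg, ...) message(sprintf(msg, ...))

  # -- stage 1: score and band every model ---------------------------------
  iv <- build_input_matrix(x)
  results_by_model <- list()
  for (m in names(models)) {
    res <- rank_and_band(toxpi_scores(iv, models[[m]]), denominator_policy)
    res$name <- x$chemicals$name[match(res$chemical_id, x$chemicals$chemical_id)]
    res$overall_score <- round(res$overall_score, 6)
    slice_cols <- attr(res, "slice_names")
    res <- res[, c("chemical_id", "name", "overall_score", "rank", "band",
                   slice_cols)]
    if (!is.null(rar) && m == "adipocyte_differentiation")
      res$RAR_score <- rar_scores(iv, rar)$rar_score[
        match(res$chemical_id, rownames(iv))]
    results_by_model[[m]] <- res
    f <- file.path(out_dir, paste0("toxpi_", m, ".tsv"))
    files[paste0("toxpi_", m)] <- write_tsv_report(res, f, seed)
  }
  stage("scored %d chemicals against %d models", nrow(x$chemicals),
        length(models))

  # -- stage 2: band matrix ------------------------------------------------
  bm <- band_matrix(results_by_model)
  files["band_matrix"] <- write_tsv_report(
    bm, file.path(out_dir, "band_matrix.tsv"), seed)

  # -- stage 3: prioritization ---------------------------------------------
  flagged <- prioritize(results_by_model)
  files["flagged"] <- write_tsv_report(
    data.frame(chemical_id = flagged),
    file.path(out_dir, "flagged_chemicals.tsv"), seed)
  stage("flagged %d chemicals in the top ~10%% of >= 1 model", length(flagged))

  # -- stage 4: similarity -------------------------------------------------
  entries <- if (similarity_mode == "binned_z") {
    pairwise_pearson(build_binned_matrix(x, coverage_filter = coverage_filter),
                     min_overlap = min_overlap)
  } else {
    pairwise_pearson_ac50(x, min_overlap = min_overlap,
                          coverage_filter = coverage_filter)
  }
  ent_out <- entries
  ent_out$pearson_r <- round(ent_out$pearson_r, 4)
  files["similarity_pairs"] <- write_tsv_report(
    ent_out, file.path(out_dir, "similarity_pairs.tsv"), seed)
  in_entries <- unique(c(entries$chem_a, entries$chem_b))
  queries <- intersect(flagged, in_entries)
  top_tables <- do.call(rbind, lapply(queries, function(q) {
    t <- top_similar(entries, q, k = top_k)
    if (nrow(t)) cbind(query = q, t) else NULL
  }))
  if (is.null(top_tables))
    top_tables <- data.frame(query = character(), rank = integer(),
                             chemical_id = character(), pearson_r = numeric(),
                             n_overlap = integer())
  files["top_similar"] <- write_tsv_report(
    top_tables, file.path(out_dir, "top_similar.tsv"), seed)
  stage("correlated %d chemical pairs (%s mode)", nrow(entries),
        similarity_mode)

  # -- stage 5: clustering -------------------------------------------------
  clustering <- NULL
  if (!is.null(cluster_model) && cluster_model %in% names(results_by_model)) {
    res <- results_by_model[[cluster_model]]
    slice_cols <- names(models[[cluster_model]]$slices)
    ss <- as.matrix(res[, slice_cols, drop = FALSE])
    rownames(ss) <- res$chemical_id
    pca <- pca_reduce(ss, threshold = pca_threshold)
    km <- kmeans_cluster(pca$coords, seed = seed, restarts = restarts)
    prof <- cluster_profiles(km, ss)
    clustering <- list(pca = pca, kmeans = km, profiles = prof)
    files["cluster_assignments"] <- write_tsv_report(
      data.frame(chemical_id = names(km$assignments),
                 cluster = unname(km$assignments)),
      file.path(out_dir, "cluster_assignments.tsv"), seed)
    files["cluster_profiles"] <- write_tsv_report(
      prof, file.path(out_dir, "cluster_profiles.tsv"), seed)
    stage("clustered %s model into %d clusters on %d retained PCs",
          cluster_model, km$k, length(pca$retained))
  }

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("toxpiscreen")),
    seed = seed,
    config = list(models = names(models),
                  denominator_policy = denominator_policy,
                  coverage_filter = coverage_filter,
                  min_overlap = min_overlap,
                  similarity_mode = similarity_mode,
                  cluster_model = cluster_model,
                  pca_threshold = pca_threshold, restarts = restarts,
                  top_k = top_k),
    outputs = lapply(stats::setNames(nm = names(files)), function(k)
      list(path = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]]))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(results_by_model = results_by_model, band_matrix = bm,
                 flagged = flagged, similarity = entries,
                 clustering = clustering, manifest = manifest,
                 manifest_path = manifest_path, files = files))
}
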