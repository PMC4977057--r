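# Synthetic screening-data generator.
#
# Emulates the structure of a sparse HTS release: a chemical library with a
# densely tested subset and a sparsely tested remainder, lognormal AC50s,
# z-scores concentrated near 0 (cytotoxic-burst background) with a minority
# of specific hits, and planted mechanism archetypes (PPARgamma agonist, GR
# agonist, monoamine-receptor binder, broad cytotoxicant) whose recovery by
# the pipeline is the generator's reason to exist.

#' Define a mechanism archetype for simulation
#'
#' @param name archetype name.
#' @param target_assay_ids assays where the archetype is specifically
#'   active; may be empty (pure background archetype).
#' @param p_active_target,p_active_background per-assay activity
#'   probabilities on target and non-target assays.
#' @param log10_ac50_mean,log10_ac50_sd log10 AC50 (uM) distribution of
#'   target hits; default mean 0 (1 uM), sd 0.5.
#' @param bg_log10_ac50_mean,bg_log10_ac50_sd AC50 distribution of
#'   background hits (weaker: default mean 1.3, about 20 uM).
#' @param z_target_mean,z_target_sd z-score distribution of target hits,
#'   truncated below at `z_floor`.
#' @param z_floor lower truncation of target z-scores (default 2.5, so
#'   planted signal survives the z <= 2 burst filter by construction).
#' @param z_background_cap background hits draw z uniformly on
#'   `[0, z_background_cap]` (default 2: burst-like, removed by the filter).
#' @return list of class `archetype_spec`.
#' @export
archetype_spec <- function(name, target_assay_ids = character(),
                           p_active_target = 0.8, p_active_background = 0.05,
                           log10_ac50_mean = 0, log10_ac50_sd = 0.5,
                           bg_log10_ac50_mean = 1.3, bg_log10_ac50_sd = 0.5,
                           z_target_mean = 4, z_target_sd = 1.5,
                           z_floor = 2.5, z_background_cap = 2) {
  stopifnot(p_active_target >= 0, p_active_target <= 1,
            p_active_background >= 0, p_active_background <= 1,
            log10_ac50_sd > 0, bg_log10_ac50_sd > 0, z_target_sd > 0,
            z_background_cap >= 0)
  structure(list(name = name,
                 target_assay_ids = as.character(target_assay_ids),
                 p_active_target = p_active_target,
                 p_active_background = p_active_background,
                 log10_ac50_mean = log10_ac50_mean,
                 log10_ac50_sd = log10_ac50_sd,
                 bg_log10_ac50_mean = bg_log10_ac50_mean,
                 bg_log10_ac50_sd = bg_log10_ac50_sd,
                 z_target_mean = z_target_mean, z_target_sd = z_target_sd,
                 z_floor = z_floor, z_background_cap = z_background_cap),
            class = "archetype_spec")
}

#' Assemble an assay panel from process models plus distractors
#'
#' @param models list of [process_model()] objects (may be empty).
#' @param n_extra_assays number of unrelated distractor assays to append.
#' @return data.frame `assay_id`, `gene_symbol` with unique ids.
#' @export
build_panel <- function(models = list(), n_extra_assays = 0) {
  ids <- unique(unlist(lapply(models, model_assay_ids), use.names = FALSE))
  if (n_extra_assays > 0)
    ids <- c(ids, sprintf("DISTRACTOR_%03d", seq_len(n_extra_assays)))
  data.frame(assay_id = ids,
             gene_symbol = sub("_[0-9]+$", "", ids),
             row.names = NULL)
}

# normal truncated below at `floor` via inverse-CDF sampling
rnorm_trunc_below <- function(n, mean, sd, floor) {
  p0 <- stats::pnorm(floor, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Simulate a ToxCast-shaped HTS dataset
#'
#' Each chemical belongs to an archetype (or is a null chemical using pure
#' background parameters). Every chemical-assay pair is active with the
#' archetype's target or background probability; active target pairs draw a
#' lognormal AC50 and a truncated-normal z-score, active background pairs
#' draw a weaker AC50 and a burst-like z in `[0, z_background_cap]`;
#' remaining pairs are tested-inactive. Chemicals are split into a densely
#' tested tier (fully tested) and a sparse tier where each pair is
#' independently masked to untested with probability `1 - sparse_coverage`.
#' Fully deterministic given `seed`.
#'
#' @param panel data.frame from [build_panel()].
#' @param archetypes list of `list(spec = archetype_spec, n = count)`.
#' @param n_null_chemicals number of null (background-only) chemicals.
#' @param dense_fraction fraction of chemicals in the dense tier.
#' @param sparse_coverage per-pair testing probability in the sparse tier.
#' @param seed integer seed.
#' @return list of class `synthetic_dataset`: `matrix` ([hts_matrix()]),
#'   `truth` (data.frame `chemical_id`, `archetype`, `tier`), `seed`.
#' @export
simulate_dataset <- function(panel, archetypes = list(), n_null_chemicals = 0,
                             dense_fraction = 0.57, sparse_coverage = 0.5,
                             seed) {
  if (missing(seed)) stop("simulate_dataset requires a seed", call. = FALSE)
  if (dense_fraction < 0 || dense_fraction > 1)
    stop("dense_fraction must be in [0, 1]", call. = FALSE)
  if (sparse_coverage < 0 || sparse_coverage > 1)
    stop("sparse_coverage must be in [0, 1]", call. = FALSE)
  stopifnot(is.data.frame(panel), "assay_id" %in% names(panel))
  for (a in archetypes) {
    stopifnot(inherits(a$spec, "archetype_spec"), a$n >= 0)
    missing_targets <- setdiff(a$spec$target_assay_ids, panel$assay_id)
    if (length(missing_targets))
      stop("archetype '", a$spec$name, "' targets assays absent from the ",
           "panel: ", paste(missing_targets, collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)

  null_spec <- archetype_spec("null")
  chems <- list(); specs <- list()
  for (a in archetypes) {
    if (a$n == 0) next
    ids <- sprintf("%s-%03d", a$spec$name, seq_len(a$n))
    chems[[length(chems) + 1L]] <-
      data.frame(chemical_id = ids, name = ids, class = a$spec$name)
    specs <- c(specs, rep(list(a$spec), a$n))
  }
  if (n_null_chemicals > 0) {
    ids <- sprintf("null-%03d", seq_len(n_null_chemicals))
    chems[[length(chems) + 1L]] <-
      data.frame(chemical_id = ids, name = ids, class = "null")
    specs <- c(specs, rep(list(null_spec), n_null_chemicals))
  }
  if (!length(chems)) stop("no chemicals requested", call. = FALSE)
  chemicals <- do.call(rbind, chems)
  n_chem <- nrow(chemicals); n_assay <- nrow(panel)

  n_dense <- round(dense_fraction * n_chem)
  tier <- rep("sparse", n_chem)
  tier[sample.int(n_chem, n_dense)] <- "dense"

  rows <- vector("list", n_chem)
  for (i in seq_len(n_chem)) {
    sp <- specs[[i]]
    is_target <- panel$assay_id %in% sp$target_assay_ids
    p <- ifelse(is_target, sp$p_active_target, sp$p_active_background)
    active <- stats::runif(n_assay) < p
    hit <- ifelse(active, "active", "inactive")
    ac50 <- z <- rep(NA_real_, n_assay)
    ta <- active & is_target
    ba <- active & !is_target
    ac50[ta] <- 10^stats::rnorm(sum(ta), sp$log10_ac50_mean, sp$log10_ac50_sd)
    z[ta] <- rnorm_trunc_below(sum(ta), sp$z_target_mean, sp$z_target_sd,
                               sp$z_floor)
    ac50[ba] <- 10^stats::rnorm(sum(ba), sp$bg_log10_ac50_mean,
                                sp$bg_log10_ac50_sd)
    z[ba] <- stats::runif(sum(ba), 0, sp$z_background_cap)
    tested <- if (tier[i] == "dense") rep(TRUE, n_assay)
              else stats::runif(n_assay) < sparse_coverage
    if (any(tested))
      rows[[i]] <- data.frame(chemical_id = chemicals$chemical_id[i],
                              assay_id = panel$assay_id[tested],
                              hit_call = hit[tested],
                              ac50_uM = ac50[tested], z_score = z[tested])
  }
  results <- do.call(rbind, rows)
  if (is.null(results))
    results <- data.frame(chemical_id = character(), assay_id = character(),
                          hit_call = character(), ac50_uM = numeric(),
                          z_score = numeric())
  structure(list(
    matrix = hts_matrix(chemicals, panel, results),
    truth = data.frame(chemical_id = chemicals$chemical_id,
                       archetype = chemicals$class, tier = tier,
                       row.names = NULL),
    seed = as.integer(seed)), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset (seed %d): %s chemicals [%s]\n", x$seed,
              nrow(x$truth),
              paste(names(table(x$truth$archetype)), table(x$truth$archetype),
                    sep = "=", collapse = ", ")))
  print(x$matrix)
  invisible(x)
}

#' Bundled simulation scenarios
#'
#' Named scenario configurations over the bundled models' panel. Each single-
#' archetype scenario plants 20 archetype chemicals among 400 nulls; the
#' `"recovery"` scenario plants all four archetypes at once (20 each + 400
#' nulls) and is the pipeline's end-to-end validation surface. Archetypes:
#' \describe{
#'   \item{pparg_agonist}{targets the PPARgamma/PPRE/RXRA endpoints shared by
#'     the adipocyte differentiation and insulin sensitivity models.}
#'   \item{gr_agonist}{targets the glucocorticoid receptor endpoints
#'     (dexamethasone-like; adipocyte differentiation).}
#'   \item{monoamine_binder}{targets serotonin/dopamine receptor and
#'     transporter endpoints (haloperidol-like; beta cell, islet, and
#'     C. elegans feeding models).}
#'   \item{broad_cytotoxicant}{high background activity with z <= 2
#'     everywhere; the burst filter should silence it to a ToxPi score of 0.}
#'   \item{null}{background-only chemicals.}
#' }
#'
#' @return named list of scenario configs (`archetypes`, `n_null_chemicals`,
#'   `dense_fraction`, `sparse_coverage`, `n_extra_assays`,
#'   `matched_model`).
#' @export
bundled_scenarios <- function() {
  pparg <- archetype_spec("pparg_agonist",
    target_assay_ids = c("PPARG_1", "PPARG_2", "PPARG_3", "PPARG_4",
                         "PPRE_1", "RXRA_1"))
  gr <- archetype_spec("gr_agonist",
    target_assay_ids = c("NR3C1_1", "NR3C1_2", "NR3C1_3", "NR3C1_4"))
  mono <- archetype_spec("monoamine_binder",
    target_assay_ids = c("DRD1_1", "DRD2_1", "DRD3_1", "DRD4_1", "DRD5_1",
                         "HTR1A_1", "HTR2A_1", "HTR2C_1", "HTR3A_1",
                         "HTR4_1", "HTR5A_1", "HTR6_1", "HTR7_1",
                         "SLC6A4_1", "SLC6A4_2"))
  cytotox <- archetype_spec("broad_cytotoxicant",
    p_active_background = 0.6, z_background_cap = 2)

  base <- list(n_null_chemicals = 400, dense_fraction = 0.57,
               sparse_coverage = 0.5, n_extra_assays = 40)
  mk <- function(archetypes, matched_model)
    c(base, list(archetypes = archetypes, matched_model = matched_model))

  list(
    pparg_agonist = mk(list(list(spec = pparg, n = 20)),
                       "adipocyte_differentiation"),
    gr_agonist = mk(list(list(spec = gr, n = 20)),
                    "adipocyte_differentiation"),
    monoamine_binder = mk(list(list(spec = mono, n = 20)),
                          "beta_cell_function"),
    broad_cytotoxicant = mk(list(list(spec = cytotox, n = 20)), NA_character_),
    null = mk(list(), NA_character_),
    recovery = c(base, list(
      archetypes = list(list(spec = pparg, n = 20), list(spec = gr, n = 20),
                        list(spec = mono, n = 20), list(spec = cytotox, n = 20)),
      matched_model = c(pparg_agonist = "adipocyte_differentiation",
                        gr_agonist = "adipocyte_differentiation",
                        monoamine_binder = "beta_cell_function")))
  )
}

#' Simulate a bundled scenario
#'
#' @param scenario a scenario name from [bundled_scenarios()] or a scenario
#'   config list of the same shape.
#' @param seed integer seed.
#' @param models models whose assays form the panel (default
#'   [bundled_models()] plus [rar_model()]).
#' @return a `synthetic_dataset` (see [simulate_dataset()]).
#' @export
simulate_scenario <- function(scenario, seed,
                              models = c(bundled_models(),
                                         list(rar = rar_model()))) {
  if (is.character(scenario)) {
    sc <- bundled_scenarios()[[scenario]]
    if (is.null(sc)) stop("unknown scenario: ", scenario, call. = FALSE)
  } else sc <- scenario
  panel <- build_panel(models, n_extra_assays = sc$n_extra_assays)
  ds <- simulate_dataset(panel, archetypes = sc$archetypes,
                         n_null_chemicals = sc$n_null_chemicals,
                         dense_fraction = sc$dense_fraction,
                         sparse_coverage = sc$sparse_coverage, seed = seed)
  ds$matched_model <- sc$matched_model
  ds
}

#' Write a synthetic dataset to disk
#'
#' Writes the HTS results CSV (via [write_hts_table()]), a truth TSV
#' (`chemical_id`, `archetype`, `tier`), and a JSON sidecar with the seed.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(hts = file.path(dir, "hts_results.csv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_hts_table(ds$matrix, paths[["hts"]])
  utils::write.table(ds$truth, paths[["truth"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(seed = ds$seed,
                            n_chemicals = nrow(ds$truth),
                            n_assays = nrow(ds$matrix$assays),
                            matched_model = ds$matched_model),
                       paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
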