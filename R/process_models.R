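# Biological-process ToxPi models: named, ordered sets of slices, each slice
# pooling one or more assay endpoints for a gene/receptor family. Slice
# weights are proportional contributions and must sum to 1; the default is
# equal weighting (1 / number of slices).

#' Construct a biological-process ToxPi model
#'
#' @param model_name model name (e.g. `"adipocyte_differentiation"`).
#' @param slices named list: each element a character vector of assay ids
#'   making up that slice. Names are the slice names.
#' @param weights optional numeric vector of positive slice weights summing
#'   to 1; defaults to equal weights.
#' @return An object of class `process_model`.
#' @export
process_model <- function(model_name, slices, weights = NULL) {
  stopifnot(is.character(model_name), length(model_name) == 1, nzchar(model_name))
  if (!length(slices)) stop("a model needs at least one slice", call. = FALSE)
  nm <- names(slices)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every slice must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("slice names must be unique within a model", call. = FALSE)
  slices <- lapply(slices, as.character)
  for (i in seq_along(slices)) {
    a <- slices[[i]]
    if (!length(a)) stop("slice '", nm[i], "' has no assays", call. = FALSE)
    if (anyDuplicated(a))
      stop("slice '", nm[i], "' lists duplicate assay ids", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- rep(1 / length(slices), length(slices))
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != length(slices) || any(!is.finite(weights)) ||
        any(weights <= 0))
      stop("weights must be positive, one per slice", call. = FALSE)
    if (abs(sum(weights) - 1) > 1e-12)
      stop("slice weights must sum to 1 (got ", format(sum(weights)), ")",
           call. = FALSE)
  }
  structure(list(model_name = model_name, slices = slices,
                 weights = stats::setNames(weights, nm)),
            class = "process_model")
}

#' @export
print.process_model <- function(x, ...) {
  cat(sprintf("process_model '%s': %d slices, %d assay endpoints\n",
              x$model_name, length(x$slices), length(model_assay_ids(x))))
  invisible(x)
}

#' All distinct assay ids referenced by a model
#' @param model a [process_model()].
#' @return character vector of assay ids.
#' @export
model_assay_ids <- function(model) {
  stopifnot(inherits(model, "process_model"))
  unique(unlist(model$slices, use.names = FALSE))
}

#' Load a model definition from JSON
#'
#' Format: `{"model_name": str, "slices": [{"slice_name": str,
#' "assay_ids": [str], "weight": number?}]}`. Omitted weights default to
#' equal weighting; if any weight is given, all must be, and they must sum
#' to 1.
#'
#' @param path path to a JSON model file.
#' @return A [process_model()].
#' @export
load_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$model_name) || is.null(j$slices))
    stop("model JSON needs 'model_name' and 'slices'", call. = FALSE)
  sl <- lapply(j$slices, function(s) unlist(s$assay_ids, use.names = FALSE))
  names(sl) <- vapply(j$slices, function(s) s$slice_name %||% "", "")
  w <- lapply(j$slices, function(s) s$weight)
  has_w <- !vapply(w, is.null, TRUE)
  if (any(has_w) && !all(has_w))
    stop("either all slices carry a weight or none do", call. = FALSE)
  process_model(j$model_name, sl,
                weights = if (all(has_w)) unlist(w) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model definition to JSON
#' @param model a [process_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "process_model"))
  slices <- lapply(seq_along(model$slices), function(i) {
    list(slice_name = names(model$slices)[i],
         assay_ids = I(model$slices[[i]]),
         weight = unname(model$weights[i]))
  })
  jsonlite::write_json(list(model_name = model$model_name, slices = slices),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

BUNDLED_MODEL_NAMES <- c("adipocyte_differentiation",
                         "feeding_behavior_rodent",
                         "feeding_behavior_celegans",
                         "insulin_sensitivity",
                         "islet_cell_function",
                         "beta_cell_function")

model_file <- function(name) {
  f <- system.file("extdata", "models", paste0(name, ".json"),
                   package = "toxpiscreen")
  if (!nzchar(f)) stop("bundled model file not found: ", name, call. = FALSE)
  f
}

#' The six bundled biological-process models
#'
#' Loads the packaged definitions of the six expert-curated metabolic-
#' disruption models: adipocyte differentiation (5 slices), feeding behavior
#' in rodents (9), feeding behavior in C. elegans (12), insulin sensitivity
#' in peripheral tissue (11), islet cell function (11), and beta cell
#' function (14). Assay ids are `<GENE>_<k>` placeholder endpoint names;
#' users screening real releases supply their own model JSON with the
#' release's endpoint names.
#'
#' @return Named list of six [process_model()] objects.
#' @export
bundled_models <- function() {
  stats::setNames(lapply(BUNDLED_MODEL_NAMES, function(n) load_model(model_file(n))),
                  BUNDLED_MODEL_NAMES)
}

#' The retinoic acid receptor (RAR) companion model
#'
#' A single-slice model over RAR agonism endpoints, scored with the same
#' machinery and reported alongside the adipocyte differentiation results:
#' RAR activation can block downstream adipogenic signaling, so a high RAR
#' score qualifies a high adipocyte score.
#'
#' @return A single-slice [process_model()].
#' @export
rar_model <- function() load_model(model_file("rar_score"))

#' Check a model's assay ids against an HTS panel
#'
#' Missing assays are legal (screening matrices are sparse); they simply
#' contribute nothing to the model's slices.
#'
#' @param model a [process_model()].
#' @param x an [hts_matrix()] (or character vector of panel assay ids).
#' @return list with `resolved` and `missing` assay-id vectors and
#'   `complete` (TRUE if nothing is missing).
#' @export
validate_against_panel <- function(model, x) {
  panel <- if (inherits(x, "hts_matrix")) x$assays$assay_id else as.character(x)
  ids <- model_assay_ids(model)
  miss <- setdiff(ids, panel)
  list(model_name = model$model_name,
       resolved = setdiff(ids, miss),
       missing = miss,
       complete = length(miss) == 0L)
}
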