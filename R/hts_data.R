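#' @keywords internal
"_PACKAGE"

# Hit-call vocabulary. "untested" is never stored: absence of a
# (chemical, assay) key in the results table encodes untested.
HIT_CALLS <- c("active", "inactive", "single_conc_presumed_inactive", "untested")

#' Construct a chemical-by-assay HTS results container
#'
#' An `hts_matrix` bundles a chemical library, an assay panel, and a sparse
#' long-format table of per-pair screening results. Each stored row is one
#' chemical-assay measurement: a hit call, and for active pairs an AC50 (in
#' micromolar) and a z-score giving the distance of the hit from the
#' chemical's cytotoxicity distribution (larger z = more specific activity).
#' Pairs with no stored row are untested.
#'
#' @param chemicals data.frame with at least `chemical_id` and `name`
#'   columns; extra columns (e.g. a `class` annotation) are kept.
#' @param assays data.frame with at least an `assay_id` column, or a
#'   character vector of assay ids.
#' @param results data.frame with columns `chemical_id`, `assay_id`,
#'   `hit_call`, `ac50_uM`, `z_score`. Rows with `hit_call = "untested"`
#'   are dropped. AC50 and z-score are required on active rows and ignored
#'   (stored as NA) otherwise.
#' @return An object of class `hts_matrix`.
#' @export
hts_matrix <- function(chemicals, assays, results) {
  if (is.character(assays)) assays <- data.frame(assay_id = assays)
  stopifnot(is.data.frame(chemicals), is.data.frame(assays), is.data.frame(results))
  if (!all(c("chemical_id", "name") %in% names(chemicals)))
    stop("`chemicals` needs columns chemical_id and name", call. = FALSE)
  if (!"assay_id" %in% names(assays))
    stop("`assays` needs an assay_id column", call. = FALSE)
  need <- c("chemical_id", "assay_id", "hit_call", "ac50_uM", "z_score")
  miss <- setdiff(need, names(results))
  if (length(miss) && !all(miss %in% c("ac50_uM", "z_score")))
    stop("`results` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (m in intersect(miss, c("ac50_uM", "z_score"))) results[[m]] <- NA_real_

  chemicals$chemical_id <- as.character(chemicals$chemical_id)
  assays$assay_id <- as.character(assays$assay_id)
  if (anyDuplicated(chemicals$chemical_id))
    stop("duplicated chemical_id in chemical library", call. = FALSE)
  if (anyDuplicated(assays$assay_id))
    stop("duplicated assay_id in assay panel", call. = FALSE)
  if (any(!nzchar(chemicals$chemical_id)) || any(!nzchar(assays$assay_id)))
    stop("empty identifiers are not allowed", call. = FALSE)

  results <- results[, need]
  results$chemical_id <- as.character(results$chemical_id)
  results$assay_id <- as.character(results$assay_id)
  results$hit_call <- as.character(results$hit_call)
  results$ac50_uM <- as.numeric(results$ac50_uM)
  results$z_score <- as.numeric(results$z_score)

  bad_call <- setdiff(unique(results$hit_call), HIT_CALLS)
  if (length(bad_call))
    stop("unknown hit_call value(s): ", paste(bad_call, collapse = ", "),
         call. = FALSE)
  results <- results[results$hit_call != "untested", , drop = FALSE]

  unknown_chem <- setdiff(results$chemical_id, chemicals$chemical_id)
  if (length(unknown_chem))
    stop("results reference unknown chemical(s): ",
         paste(utils::head(unknown_chem, 5), collapse = ", "), call. = FALSE)
  unknown_assay <- setdiff(results$assay_id, assays$assay_id)
  if (length(unknown_assay))
    stop("results reference unknown assay(s): ",
         paste(utils::head(unknown_assay, 5), collapse = ", "), call. = FALSE)

  key <- paste(results$chemical_id, results$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate result for pair (",
         sub("\r", ", ", dup, fixed = TRUE), ")", call. = FALSE)
  }

  act <- results$hit_call == "active"
  bad <- act & (!is.finite(results$ac50_uM) | !is.finite(results$z_score))
  if (any(bad))
    stop("active row(s) missing ac50_uM or z_score, e.g. pair (",
         results$chemical_id[bad][1], ", ", results$assay_id[bad][1], ")",
         call. = FALSE)
  if (any(act & results$ac50_uM <= 0))
    stop("nonpositive ac50_uM on active row(s)", call. = FALSE)
  # permissive read: potency/z on non-active rows is dropped, not an error
  results$ac50_uM[!act] <- NA_real_
  results$z_score[!act] <- NA_real_

  rownames(chemicals) <- rownames(assays) <- rownames(results) <- NULL
  structure(list(chemicals = chemicals, assays = assays, results = results),
            class = "hts_matrix")
}

#' @export
print.hts_matrix <- function(x, ...) {
  cat(sprintf("hts_matrix: %d chemicals x %d assays, %d stored results (%.1f%% tested)\n",
              nrow(x$chemicals), nrow(x$assays), nrow(x$results),
              100 * nrow(x$results) / max(1, nrow(x$chemicals) * nrow(x$assays))))
  invisible(x)
}

#' Read an HTS results table from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `chemical_id`,
#' `chemical_name`, `assay_id`, `hit_call`, `ac50_uM`, `z_score`. Empty
#' strings encode missing numbers. Rows with `hit_call = "untested"` are
#' dropped on load, so a file with or without explicit untested rows loads
#' to the same object.
#'
#' @param path path to a CSV file.
#' @return An [hts_matrix()].
#' @export
load_hts_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("chemical_id", "chemical_name", "assay_id", "hit_call",
            "ac50_uM", "z_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("HTS table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  chem <- unique(df[, c("chemical_id", "chemical_name")])
  names(chem)[2] <- "name"
  res <- df[, c("chemical_id", "assay_id", "hit_call", "ac50_uM", "z_score")]
  res$ac50_uM <- suppressWarnings(as.numeric(ifelse(res$ac50_uM == "", NA, res$ac50_uM)))
  res$z_score <- suppressWarnings(as.numeric(ifelse(res$z_score == "", NA, res$z_score)))
  hts_matrix(chem, unique(df$assay_id), res)
}

#' Write an HTS results table to CSV
#'
#' Inverse of [load_hts_table()]: numbers are rendered with round-trip
#' precision so that loading the written file reproduces the stored results
#' exactly.
#'
#' @param x an [hts_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hts_table <- function(x, path) {
  stopifnot(inherits(x, "hts_matrix"))
  res <- x$results
  nm <- x$chemicals$name[match(res$chemical_id, x$chemicals$chemical_id)]
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(chemical_id = res$chemical_id, chemical_name = nm,
                    assay_id = res$assay_id, hit_call = res$hit_call,
                    ac50_uM = fmt(res$ac50_uM), z_score = fmt(res$z_score),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Restrict an HTS matrix to selected chemicals and/or assays
#'
#' @param x an [hts_matrix()].
#' @param chemicals,assays character vectors of ids to keep; `NULL` keeps all.
#' @return An [hts_matrix()] restricted to the requested ids; untested status
#'   is preserved as absence.
#' @export
subset_hts <- function(x, chemicals = NULL, assays = NULL) {
  stopifnot(inherits(x, "hts_matrix"))
  if (is.null(chemicals)) chemicals <- x$chemicals$chemical_id
  if (is.null(assays)) assays <- x$assays$assay_id
  bad <- setdiff(chemicals, x$chemicals$chemical_id)
  if (length(bad))
    stop("unknown chemical id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(assays, x$assays$assay_id)
  if (length(bad))
    stop("unknown assay id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  keep <- x$results$chemical_id %in% chemicals & x$results$assay_id %in% assays
  hts_matrix(x$chemicals[x$chemicals$chemical_id %in% chemicals, , drop = FALSE],
             x$assays[x$assays$assay_id %in% assays, , drop = FALSE],
             x$results[keep, , drop = FALSE])
}

#' Testing-coverage summary of an HTS matrix
#'
#' Fraction tested counts any stored result (active, inactive, or presumed
#' inactive); untested pairs are the complement.
#'
#' @param x an [hts_matrix()].
#' @return A list with `n_chemicals`, `n_assays`, `fraction_tested` (overall),
#'   and per-chemical / per-assay data frames of tested fractions.
#' @export
coverage_stats <- function(x) {
  stopifnot(inherits(x, "hts_matrix"))
  nc <- nrow(x$chemicals); na <- nrow(x$assays)
  tc <- table(factor(x$results$chemical_id, levels = x$chemicals$chemical_id))
  ta <- table(factor(x$results$assay_id, levels = x$assays$assay_id))
  list(
    n_chemicals = nc,
    n_assays = na,
    fraction_tested = nrow(x$results) / max(1, nc * na),
    by_chemical = data.frame(chemical_id = x$chemicals$chemical_id,
                             fraction_tested = if (na > 0) as.numeric(tc) / na else 0,
                             row.names = NULL),
    by_assay = data.frame(assay_id = x$assays$assay_id,
                          fraction_tested = if (nc > 0) as.numeric(ta) / nc else 0,
                          row.names = NULL)
  )
}
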