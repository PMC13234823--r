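# Reading and writing feature tables, annotations, sample metadata and
# prediction tables. All files are header-ed delimited text (comma or tab,
# auto-detected). Missing intensity cells ("", NA, NaN) are preserved as NA
# and never imputed at this layer.

.defaultSchema <- list(feature_id = "feature_id", mz = "mz", rt = "rt",
                       neutral_mass = "neutral_mass")

#' Read a feature table from delimited text
#'
#' Expected layout: one row per feature with columns `feature_id`, `mz`,
#' `rt`, optionally `neutral_mass`, followed by one intensity column per
#' sample. Column names can be remapped through `schema`.
#'
#' @param path path to a comma- or tab-delimited file with a header row.
#' @param grouped logical; `TRUE` when rows are grouped analytes carrying a
#'   neutral mass.
#' @param polarity ESI mode of the assay, `"positive"` or `"negative"`.
#' @param schema named list remapping the reserved column names
#'   (`feature_id`, `mz`, `rt`, `neutral_mass`) to the file's headers.
#' @param rtUnit `"seconds"` (default) or `"minutes"`; minute-scale inputs
#'   are converted so retention times are always seconds internally.
#' @return A [LipidFeatureSet-class].
#' @seealso [writePredictions()], [readAnnotations()]
#' @export
readFeatureTable <- function(path, grouped = FALSE, polarity = "positive",
                             schema = NULL, rtUnit = c("seconds", "minutes")) {
  rtUnit <- match.arg(rtUnit)
  sc <- utils::modifyList(.defaultSchema, as.list(schema %||% list()))
  df <- .readDelim(path)
  need <- c(sc$feature_id, sc$mz, sc$rt)
  if (grouped) need <- c(need, sc$neutral_mass)
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ids <- as.character(df[[sc$feature_id]])
  if (anyDuplicated(ids))
    stop("validation error: duplicate feature_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  reserved <- intersect(unlist(sc), colnames(df))
  sample_cols <- setdiff(colnames(df), reserved)
  if (length(sample_cols) < 2L)
    stop("validation error: need >= 2 sample intensity columns")
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(m < 0, na.rm = TRUE))
    stop("validation error: negative intensity values present")
  rt <- as.numeric(df[[sc$rt]])
  if (rtUnit == "minutes") rt <- rt * 60
  nm <- if (sc$neutral_mass %in% colnames(df))
    as.numeric(df[[sc$neutral_mass]]) else NULL
  LipidFeatureSet(m, mz = as.numeric(df[[sc$mz]]), rt = rt,
                  neutralMass = nm, grouped = grouped, polarity = polarity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature table to delimited text
#'
#' Inverse of [readFeatureTable()]: columns `feature_id`, `mz`, `rt`,
#' `neutral_mass` (grouped tables only), then one intensity column per
#' sample; missing cells are written as `NA`.
#'
#' @param featureSet a [LipidFeatureSet-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(featureSet, path) {
  out <- data.frame(feature_id = featureIds(featureSet),
                    mz = unname(featureMz(featureSet)),
                    rt = unname(featureRt(featureSet)),
                    stringsAsFactors = FALSE)
  nm <- neutralMass(featureSet)
  if (!is.null(nm)) out$neutral_mass <- unname(nm)
  out <- cbind(out, as.data.frame(intensityMatrix(featureSet)))
  .writeDelim(out, path)
  invisible(path)
}

#' Read ground-truth subclass annotations
#'
#' Two-column delimited text (`feature_id`, `subclass`). Main classes are
#' filled from the ontology; subclasses absent from the ontology are kept
#' but flagged with a warning.
#'
#' @param path delimited text with a header row.
#' @param ontology named character vector subclass -> main class (e.g.
#'   [dbOntology()]).
#' @param featureSet optional [LipidFeatureSet-class]; when given, every
#'   annotated feature_id must exist in it.
#' @return `data.frame` with columns `feature_id`, `subclass`,
#'   `main_class`, `known_subclass`.
#' @export
readAnnotations <- function(path, ontology, featureSet = NULL) {
  df <- .readDelim(path)
  if (nrow(df) == 0L)
    return(data.frame(feature_id = character(), subclass = character(),
                      main_class = character(), known_subclass = logical()))
  if (!all(c("feature_id", "subclass") %in% colnames(df)))
    stop("schema error: annotations need columns feature_id, subclass")
  out <- data.frame(feature_id = as.character(df$feature_id),
                    subclass = as.character(df$subclass),
                    stringsAsFactors = FALSE)
  out$main_class <- unname(ontology[out$subclass])
  out$known_subclass <- !is.na(out$main_class)
  if (any(!out$known_subclass))
    warning("subclass(es) absent from ontology: ",
            paste(unique(out$subclass[!out$known_subclass]), collapse = ", "))
  if (!is.null(featureSet)) {
    bad <- setdiff(out$feature_id, featureIds(featureSet))
    if (length(bad))
      stop("validation error: annotated feature_id(s) not in feature table: ",
           paste(bad, collapse = ", "))
  }
  out
}

#' Read sample metadata (phenotype and covariates)
#'
#' @param path delimited text with columns `sample_id`, `phenotype` and any
#'   further covariate columns (e.g. age, sex).
#' @param featureSet optional [LipidFeatureSet-class]; sample ids must then
#'   match its sample axis.
#' @return `data.frame` with rownames = sample_id.
#' @export
readSampleMetadata <- function(path, featureSet = NULL) {
  df <- .readDelim(path)
  if (!"sample_id" %in% colnames(df))
    stop("schema error: metadata needs a sample_id column")
  rownames(df) <- as.character(df$sample_id)
  if (!is.null(featureSet)) {
    bad <- setdiff(colnames(featureSet), rownames(df))
    if (length(bad))
      stop("validation error: samples without metadata: ",
           paste(bad, collapse = ", "))
    df <- df[colnames(featureSet), , drop = FALSE]
  }
  df
}

#' Write subclass predictions (and quality scores) to delimited text
#'
#' One row per feature with columns `feature_id`, `subclass`, `main_class`,
#' `score`, `tied`, `lsi`, `pcor`, `product`. Unclassified features carry
#' the sentinel `"unclassified"` in the class columns; undefined quality
#' values are written as `NA`.
#'
#' @param predictions prediction `data.frame` from [predictClasses()].
#' @param path output path.
#' @param quality optional quality `data.frame` from [qualityScores()].
#' @return the path, invisibly.
#' @export
writePredictions <- function(predictions, path, quality = NULL) {
  out <- data.frame(
    feature_id = predictions$feature_id,
    subclass = ifelse(is.na(predictions$subclass), "unclassified",
                      predictions$subclass),
    main_class = ifelse(is.na(predictions$main_class), "unclassified",
                        predictions$main_class),
    score = predictions$score,
    tied = predictions$tied,
    stringsAsFactors = FALSE
  )
  if (!is.null(quality)) {
    i <- match(out$feature_id, quality$feature_id)
    out$lsi <- quality$lsi_scaled[i]
    out$pcor <- quality$pcor_transformed[i]
    out$product <- quality$product[i]
  } else {
    out$lsi <- out$pcor <- out$product <- NA_real_
  }
  .writeDelim(out, path)
  invisible(path)
}

#' Read back a predictions file written by [writePredictions()]
#'
#' The `"unclassified"` sentinel is converted back to `NA`.
#' @param path file written by [writePredictions()].
#' @return `data.frame` with the eight prediction/quality columns.
#' @export
readPredictions <- function(path) {
  df <- .readDelim(path)
  df$subclass[df$subclass == "unclassified"] <- NA
  df$main_class[df$main_class == "unclassified"] <- NA
  df$tied <- as.logical(df$tied)
  df
}
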