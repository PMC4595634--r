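# FeatureTable: the raw observational unit of an untargeted LC-MS
# footprinting experiment — spectral features (m/z, RT, polarity) by
# samples, holding integrated peak areas in arbitrary ion counts.

#' Construct a feature table
#'
#' @param features data.frame with columns feature_id, mz, rt, polarity.
#' @param intensities Numeric matrix of peak areas, rows = features (in the
#'   same order / rownames = feature_id), columns = samples.
#' @return Object of class `feature_table`: a list with elements
#'   `features` and `intensities`.
#' @export
feature_table <- function(features, intensities) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("feature_id", "mz", "rt", "polarity")
  missing <- setdiff(req, names(features))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "))
  }
  features$feature_id <- as.character(features$feature_id)
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- features$feature_id
  }
  if (anyDuplicated(features$feature_id)) {
    stop("duplicated feature_id values")
  }
  if (!identical(rownames(intensities), features$feature_id)) {
    intensities <- intensities[features$feature_id, , drop = FALSE]
  }
  validate_feature_table(
    structure(list(features = features, intensities = intensities),
              class = "feature_table")
  )
}

validate_feature_table <- function(ft) {
  features <- ft$features
  intens <- ft$intensities
  stopifnot(all(features$mz > 0), all(features$rt >= 0))
  if (!all(features$polarity %in% c("positive", "negative"))) {
    stop("polarity must be 'positive' or 'negative'")
  }
  if (any(!is.finite(intens))) stop("non-finite peak areas")
  if (any(intens < 0)) stop("negative peak areas")
  if (is.null(colnames(intens))) stop("intensity matrix lacks sample ids")
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      ncol(x$intensities), " samples\n", sep = "")
  pol <- table(x$features$polarity)
  cat("  polarity:", paste(names(pol), pol, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of features / samples
#' @param ft A `feature_table`.
#' @return Integer count.
#' @export
n_features <- function(ft) nrow(ft$features)

#' @rdname n_features
#' @export
n_samples <- function(ft) ncol(ft$intensities)

.delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read a feature table from TSV/CSV
#'
#' Accepts either the long dialect (columns `feature_id, mz, rt, polarity,
#' sample_id, area`; one row per feature x sample) or the wide dialect
#' (columns `feature_id, mz, rt, polarity` followed by one column per
#' sample). The dialect is detected from the header; the delimiter from
#' the file extension (`.csv` = comma, otherwise tab).
#'
#' @param path Path to the table.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("feature_id", "mz", "rt", "polarity")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("feature table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  long <- all(c("sample_id", "area") %in% names(df))
  if (long) {
    if (any(df$area < 0, na.rm = TRUE)) stop("negative areas in ", path)
    key <- paste(df$feature_id, df$sample_id)
    if (anyDuplicated(key)) {
      stop("duplicate (feature_id, sample_id) rows in ", path, ": ",
           paste(utils::head(key[duplicated(key)], 3L), collapse = "; "))
    }
    feats <- unique(df[, req])
    if (anyDuplicated(feats$feature_id)) {
      stop("inconsistent feature annotations for a feature_id in ", path)
    }
    samples <- unique(df$sample_id)
    intens <- matrix(0, nrow(feats), length(samples),
                     dimnames = list(feats$feature_id, samples))
    intens[cbind(match(df$feature_id, feats$feature_id),
                 match(df$sample_id, samples))] <- df$area
    feature_table(feats, intens)
  } else {
    sample_cols <- setdiff(names(df), req)
    if (!length(sample_cols)) stop("no sample columns in ", path)
    intens <- as.matrix(df[, sample_cols, drop = FALSE])
    rownames(intens) <- as.character(df$feature_id)
    feature_table(df[, req], intens)
  }
}

#' Write a feature table
#'
#' @param ft A `feature_table`.
#' @param path Output path (`.csv` = comma, otherwise tab).
#' @param dialect `"long"` or `"wide"`.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(ft, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  sep <- .delim_for(path)
  if (dialect == "wide") {
    df <- cbind(ft$features, as.data.frame(ft$intensities))
  } else {
    samples <- colnames(ft$intensities)
    df <- data.frame(
      feature_id = rep(ft$features$feature_id, times = length(samples)),
      mz = rep(ft$features$mz, times = length(samples)),
      rt = rep(ft$features$rt, times = length(samples)),
      polarity = rep(ft$features$polarity, times = length(samples)),
      sample_id = rep(samples, each = nrow(ft$features)),
      area = as.vector(ft$intensities),
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate sample metadata
#'
#' The metadata table declares the role of every sample (`control`,
#' `spent`, `cell_extract`, `soil_water`), the isolate and medium of spent
#' samples, the control group pairing spent samples to their matched
#' uninoculated controls, and the timepoint (minutes after wetting) of
#' soil-water samples.
#'
#' @param path Path to a TSV/CSV with columns sample_id, role, isolate_id,
#'   medium_id, control_group_id, timepoint, replicate_index.
#' @return Validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  sep <- .delim_for(path)
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  validate_sample_metadata(meta)
}

#' Validate sample metadata
#' @param meta Metadata data.frame (see [read_sample_metadata()]).
#' @return The metadata, invisibly checked.
#' @export
validate_sample_metadata <- function(meta) {
  req <- c("sample_id", "role")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop("sample metadata lacks columns: ",
         paste(missing, collapse = ", "))
  }
  for (col in c("isolate_id", "medium_id", "control_group_id",
                "timepoint", "replicate_index")) {
    if (!col %in% names(meta)) meta[[col]] <- NA
  }
  roles <- c("control", "spent", "cell_extract", "soil_water")
  bad <- setdiff(unique(meta$role), roles)
  if (length(bad)) stop("unknown sample role(s): ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id")
  spent <- meta[meta$role == "spent", , drop = FALSE]
  ctrl <- meta[meta$role == "control", , drop = FALSE]
  if (nrow(spent)) {
    for (g in unique(spent$control_group_id)) {
      if (is.na(g)) stop("spent sample lacks control_group_id")
      n <- sum(ctrl$control_group_id == g, na.rm = TRUE)
      if (n < 2L) {
        stop("control group '", g, "' resolves to ", n,
             " control sample(s); >= 2 required")
      }
    }
  }
  meta
}

#' Write sample metadata
#' @inheritParams validate_sample_metadata
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  sep <- .delim_for(path)
  utils::write.table(meta, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
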