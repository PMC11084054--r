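#' Sample-by-feature tables
#'
#' A `feature_table` is a dense numeric matrix with samples in rows and
#' features in columns, tagged with the kind of measurement it holds.
#' All functions in this package use this single orientation internally;
#' readers transpose on the way in when told the file stores features in
#' rows.
#'
#' @param values numeric matrix, samples x features, with row and column
#'   names set to sample and feature identifiers.
#' @param kind one of `"counts"`, `"relabund"`, `"intensity"`, `"clr"`,
#'   `"int_transformed"`, `"ko_relabund"`.
#' @param feature_meta optional data.frame of per-feature annotation
#'   (e.g. taxonomy string, metabolite super-pathway, KO pathway) with
#'   rownames matching feature ids, or a named character vector.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, kind = c("counts", "relabund", "intensity",
                                           "clr", "int_transformed",
                                           "ko_relabund"),
                          feature_meta = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x features)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers")
  obs <- values[!is.na(values)]
  if (kind %in% c("counts", "relabund", "intensity", "ko_relabund") &&
      any(obs < 0))
    stop(sprintf("negative values are not allowed for kind '%s'", kind))
  if (kind == "relabund") {
    rs <- rowSums(values, na.rm = TRUE)
    if (any(abs(rs - 1) > 1e-8))
      stop("relative-abundance rows must sum to 1 (within 1e-8)")
  }
  if (is.character(feature_meta))
    feature_meta <- data.frame(annotation = feature_meta,
                               row.names = names(feature_meta))
  if (!is.null(feature_meta) &&
      !all(rownames(feature_meta) %in% colnames(values)))
    stop("feature_meta rownames must be a subset of feature ids")
  structure(list(values = values, kind = kind, feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d samples x %d features\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname feature_table
#' @export
feature_ids <- function(x) colnames(x$values)

#' Subset a feature table by sample and/or feature identifiers
#'
#' @param x a `feature_table`.
#' @param samples,features character vectors of identifiers to retain (in
#'   the given order); `NULL` keeps everything.
#' @return a `feature_table`.
#' @export
ft_subset <- function(x, samples = NULL, features = NULL) {
  v <- x$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(v))
    if (length(missing))
      stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(v))
    if (length(missing))
      stop("unknown feature ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, features, drop = FALSE]
  }
  fm <- x$feature_meta
  if (!is.null(fm))
    fm <- fm[intersect(rownames(fm), colnames(v)), , drop = FALSE]
  out <- x
  out$values <- v
  out$feature_meta <- fm
  out
}

#' Read a feature table from TSV or BIOM
#'
#' TSV files must be tab-delimited with a header row; the first column
#' holds identifiers. BIOM files (`.biom`, read through the `biomformat`
#' package) follow the BIOM convention of features in rows, samples in
#' columns, and are transposed on the way in.
#'
#' @param path path to a `.tsv`/`.txt` or `.biom` file.
#' @param kind measurement kind, see [feature_table()].
#' @param orientation for TSV input: `"samples_rows"` (default; first
#'   column = sample ids, header = feature ids) or `"features_rows"`
#'   (transposed on read). `"auto"` is accepted only for BIOM input, whose
#'   orientation is fixed by the format; for TSV it is ambiguous and
#'   raises an error.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, kind = "counts",
                               orientation = c("samples_rows",
                                               "features_rows", "auto")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    values <- t(m)  # BIOM stores features x samples
  } else {
    if (orientation == "auto")
      stop("orientation 'auto' is ambiguous for TSV input; declare ",
           "'samples_rows' or 'features_rows'")
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE, comment.char = "",
                            quote = "")
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad))
      stop("non-numeric cells in column(s): ",
           paste(utils::head(names(df)[bad], 5), collapse = ", "))
    values <- as.matrix(df)
    if (orientation == "features_rows") values <- t(values)
  }
  storage.mode(values) <- "double"
  feature_table(values, kind = kind)
}

#' Write a feature table to TSV
#'
#' Samples in rows, features in columns, first column `sample_id`.
#'
#' @param x a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align omics layers on their shared samples
#'
#' Restricts every table and the metadata to the intersection of their
#' sample identifiers, preserving the metadata's original sample order.
#' This is how each analysis set (e.g. participants with concurrent
#' microbiome and metabolome data) is carved out of partially overlapping
#' layers.
#'
#' @param tables a named list of `feature_table`s.
#' @param meta a data.frame of per-sample metadata with a `sample_id`
#'   column (or sample ids as rownames).
#' @return a list with elements `tables` (aligned list), `meta` (aligned
#'   data.frame) and `layer_n` (named integer vector of per-layer sample
#'   counts before alignment).
#' @export
align_samples <- function(tables, meta) {
  if (!length(tables)) stop("at least one table is required")
  stopifnot(all(vapply(tables, inherits, logical(1), "feature_table")))
  if (!"sample_id" %in% names(meta)) {
    meta <- data.frame(sample_id = rownames(meta), meta,
                       check.names = FALSE, stringsAsFactors = FALSE)
  }
  layer_n <- vapply(tables, function(t) nrow(t$values), integer(1))
  common <- Reduce(intersect, lapply(tables, sample_ids), meta$sample_id)
  if (!length(common)) stop("empty sample intersection across layers")
  keep <- meta$sample_id[meta$sample_id %in% common]  # meta order wins
  list(tables = lapply(tables, ft_subset, samples = keep),
       meta = meta[match(keep, meta$sample_id), , drop = FALSE],
       layer_n = c(layer_n, meta = nrow(meta)))
}
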