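#' Construct a clinical table
#'
#' A `clinical_table` holds a cases x descriptors matrix of numeric clinical
#' variables in raw units, together with an explicit missingness mask.
#' Masked entries are stored as `NA` in `values` so they can never leak into
#' a computation.
#'
#' @param values Numeric matrix, one row per case, one column per descriptor.
#'   `NA` entries are treated as missing.
#' @param descriptor_names Character vector of unique, non-empty descriptor
#'   names; defaults to `colnames(values)`.
#' @param case_ids Optional case labels; defaults to `rownames(values)` or
#'   `"case_1"`, `"case_2"`, ...
#' @param missing_mask Logical matrix of the same shape as `values`
#'   (`TRUE` = absent). Defaults to `is.na(values)`.
#'
#' @return An object of class `clinical_table` with fields `values`,
#'   `descriptor_names`, `case_ids`, `missing_mask`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("BMI", "HbA1c", "EAG")))
#' clinical_table(m)
clinical_table <- function(values, descriptor_names = colnames(values),
                           case_ids = rownames(values),
                           missing_mask = is.na(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L)
    stop("a clinical table needs at least one case", call. = FALSE)
  if (ncol(values) < 2L)
    stop("a clinical table needs at least two descriptors", call. = FALSE)
  if (is.null(descriptor_names))
    stop("descriptor names are required (set colnames or pass descriptor_names)",
         call. = FALSE)
  descriptor_names <- as.character(descriptor_names)
  if (length(descriptor_names) != ncol(values))
    stop("length(descriptor_names) must equal ncol(values)", call. = FALSE)
  if (any(!nzchar(descriptor_names)))
    stop("descriptor names must be non-empty", call. = FALSE)
  dup <- unique(descriptor_names[duplicated(descriptor_names)])
  if (length(dup))
    stop("duplicate descriptor names: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(nrow(values)))
  case_ids <- as.character(case_ids)
  if (length(case_ids) != nrow(values))
    stop("length(case_ids) must equal nrow(values)", call. = FALSE)
  if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values)))
    stop("`missing_mask` must be a logical matrix with the shape of `values`",
         call. = FALSE)
  missing_mask <- missing_mask | is.na(values)
  values[missing_mask] <- NA_real_
  if (any(!is.finite(values[!missing_mask])))
    stop("observed values must be finite", call. = FALSE)
  dimnames(values) <- list(case_ids, descriptor_names)
  dimnames(missing_mask) <- dimnames(values)
  structure(
    list(values = values, descriptor_names = descriptor_names,
         case_ids = case_ids, missing_mask = missing_mask),
    class = "clinical_table"
  )
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("<%s> %d cases x %d descriptors, %d missing cells\n",
              class(x)[1L], nrow(x$values), ncol(x$values),
              sum(x$missing_mask)))
  cat("descriptors:", paste(utils::head(x$descriptor_names, 8L),
                            collapse = ", "),
      if (length(x$descriptor_names) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.clinical_table <- function(x) dim(x$values)

default_missing_tokens <- c("", "na", "nan")

#' Read a clinical table from a delimited text file
#'
#' The first row must be a header of descriptor names; every following row is
#' one case. Cells are numeric ('.' decimal separator) or one of the missing
#' tokens (matched case-insensitively after trimming whitespace).
#'
#' @param path Path to a CSV/TSV file. The separator is inferred from the
#'   extension (`.tsv`/`.tab` = tab, otherwise comma) unless `sep` is given.
#' @param missing_tokens Character vector of tokens that mark a missing cell.
#'   Default: empty cell, `"NA"`, `"NaN"` (case-insensitive).
#' @param sep Field separator; `NULL` to infer from the extension.
#' @param case_id_column If `TRUE`, the first column holds case identifiers
#'   rather than a descriptor.
#'
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path, missing_tokens = c("", "NA", "NaN"),
                                sep = NULL, case_id_column = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) < 2L) stop("file has no data rows: ", path, call. = FALSE)
  header <- trimws(as.character(raw[1L, ]))
  body <- raw[-1L, , drop = FALSE]
  case_ids <- NULL
  if (isTRUE(case_id_column)) {
    case_ids <- as.character(body[[1L]])
    header <- header[-1L]
    body <- body[, -1L, drop = FALSE]
  }
  dup <- unique(header[duplicated(header)])
  if (length(dup))
    stop("duplicate descriptor names in header: ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (length(header) < 2L)
    stop("fewer than 2 descriptors in ", path, call. = FALSE)
  tokens <- tolower(trimws(missing_tokens))
  n <- nrow(body); d <- length(header)
  vals <- matrix(NA_real_, n, d)
  mask <- matrix(FALSE, n, d)
  for (j in seq_len(d)) {
    cell <- trimws(as.character(body[[j]]))
    is_missing <- tolower(cell) %in% tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & !is.finite(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   cell[i], i, header[j]), call. = FALSE)
    }
    vals[, j] <- num
    mask[, j] <- is_missing
  }
  colnames(vals) <- header
  clinical_table(vals, descriptor_names = header, case_ids = case_ids,
                 missing_mask = mask)
}

#' Write a clinical table to a delimited text file
#'
#' Inverse of [read_clinical_table()]: masked cells are written as empty
#' fields, so a round trip preserves values, mask and names.
#'
#' @param table A [clinical_table()].
#' @param path Output file path.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @param case_id_column If `TRUE`, write case identifiers as a first column
#'   named `case_id`.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(table, path, sep = NULL,
                                 case_id_column = FALSE) {
  stopifnot(inherits(table, "clinical_table"))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(table$values)
  if (isTRUE(case_id_column))
    df <- cbind(case_id = table$case_ids, df)
  utils::write.table(df, path, sep = sep, na = "", row.names = FALSE,
                     col.names = TRUE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Standardize the descriptors of a clinical table
#'
#' Two modes, matching the two normalizations used in the workflow:
#' `"scale_only"` divides each descriptor by its sample standard deviation
#' (the normalization applied before the combinatorial search), while
#' `"z_score"` additionally subtracts the descriptor mean (the conventional
#' z-standardization used for confirmatory hierarchical clustering).
#' Statistics are computed over the observed values of each full column; the
#' mask is unchanged.
#'
#' @param table A [clinical_table()].
#' @param mode `"scale_only"` (default) or `"z_score"`.
#' @return A `standardized_table` (also a `clinical_table`) with extra fields
#'   `scale_factors` (per-descriptor SD used), `centers` (per-descriptor mean
#'   subtracted; zeros for `scale_only`) and `mode`.
#' @export
#' @examples
#' tab <- clinical_table(cbind(a = c(2, 4, 6), b = c(1, 2, 4)))
#' standardize(tab, "scale_only")$values[, "a"]  # 1 2 3
standardize <- function(table, mode = c("scale_only", "z_score")) {
  stopifnot(inherits(table, "clinical_table"))
  mode <- match.arg(mode)
  v <- table$values
  n_obs <- colSums(!table$missing_mask)
  sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
  bad <- n_obs < 2L | !is.finite(sds) | sds <= 0
  if (any(bad))
    stop("descriptor(s) with fewer than 2 observed values or zero spread: ",
         paste(table$descriptor_names[bad], collapse = ", "), call. = FALSE)
  centers <- if (mode == "z_score") colMeans(v, na.rm = TRUE)
             else rep(0, ncol(v))
  z <- sweep(sweep(v, 2L, centers, "-"), 2L, sds, "/")
  out <- clinical_table(z, descriptor_names = table$descriptor_names,
                        case_ids = table$case_ids,
                        missing_mask = table$missing_mask)
  out$scale_factors <- stats::setNames(sds, table$descriptor_names)
  out$centers <- stats::setNames(centers, table$descriptor_names)
  out$mode <- mode
  class(out) <- c("standardized_table", class(out))
  out
}

#' Summarize missingness of a clinical table
#'
#' @param table A [clinical_table()].
#' @return A list with `per_descriptor` and `per_case` missing counts, the
#'   total `n_missing`, and `mean_per_case`.
#' @export
missing_summary <- function(table) {
  stopifnot(inherits(table, "clinical_table"))
  per_desc <- colSums(table$missing_mask)
  per_case <- rowSums(table$missing_mask)
  list(per_descriptor = stats::setNames(per_desc, table$descriptor_names),
       per_case = stats::setNames(per_case, table$case_ids),
       n_missing = sum(per_desc),
       mean_per_case = mean(per_case))
}
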