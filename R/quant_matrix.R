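#' Quantification matrix
#'
#' The canonical in-memory container for a protein-group quantification
#' matrix: a numeric samples x proteins matrix in which `NA` marks a
#' missing (not quantified) entry. Values are raw intensities on input and
#' base-10 log intensities after [log10_transform()]; the `transform` flag
#' records which. Sample and protein identifiers are opaque strings and must
#' be unique.
#'
#' @param values Numeric matrix, samples in rows, proteins in columns, with
#'   dimnames giving sample and protein identifiers. `NA` marks missingness.
#' @param transform Either `"raw"` or `"log10"`.
#' @return A `quant_matrix` object.
#' @examples
#' m <- matrix(c(1000, 10, NA, 100), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("P1", "P2")))
#' qm <- quant_matrix(m)
#' log10_transform(qm)
#' @export
quant_matrix <- function(values, transform = c("raw", "log10")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry sample IDs as rownames and protein IDs as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("Duplicate sample IDs: ", paste(dups, collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dups <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("Duplicate protein IDs: ", paste(dups, collapse = ", ")))
  }
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) abort("All observed values must be finite.")
  if (transform == "raw" && any(obs <= 0)) {
    abort("Raw intensities must be positive; mark non-positive entries missing (NA).")
  }
  structure(list(values = values, transform = transform), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<quant_matrix> %d samples x %d proteins (%s scale), %.1f%% missing\n",
    nrow(v), ncol(v), x$transform, 100 * mean(is.na(v))
  ))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Sample and protein identifiers of a quantification matrix
#' @param m A [quant_matrix()].
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname sample_ids
#' @export
protein_ids <- function(m) colnames(m$values)

#' Subset a quantification matrix
#'
#' Standard `[` subsetting by sample and/or protein, preserving the
#' missingness mask and transform state.
#'
#' @param x A `quant_matrix`.
#' @param i,j Sample / protein indices (numeric, logical or names).
#' @param ... Ignored.
#' @export
`[.quant_matrix` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  quant_matrix(v[i, j, drop = FALSE], transform = x$transform)
}

#' @describeIn quant_matrix long-format view: one row per observed or
#'   missing entry, columns `sample_id`, `protein_id`, `intensity`,
#'   `missing`.
#' @param x A `quant_matrix`.
#' @param ... Ignored.
#' @exportS3Method generics::tidy
tidy.quant_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    sample_id = rep(rownames(v), times = ncol(v)),
    protein_id = rep(colnames(v), each = nrow(v)),
    intensity = as.vector(v),
    missing = is.na(as.vector(v))
  )
}

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a wide protein-group quantification matrix
#'
#' Reads the wide TSV/CSV dialect exported by protein-group search software:
#' one header row, first column identifiers. `orientation` declares whether
#' rows are proteins (the common export, first column = protein IDs,
#' remaining columns = sample IDs) or samples; the in-memory representation
#' is always samples x proteins. Cells matching `missing_codes` (after
#' whitespace trimming), and by default any non-positive intensity, are
#' marked missing, since absence is commonly encoded as 0 or blank and a
#' non-positive value cannot be log10-transformed.
#'
#' @param path Path to a delimited text file (`.csv` comma, otherwise tab).
#' @param orientation `"proteins_as_rows"` (default) or `"samples_as_rows"`.
#' @param missing_codes Character tokens treated as missing.
#' @param nonpositive_missing Mark numeric values <= 0 as missing (default
#'   `TRUE`). With `FALSE`, a non-positive cell is an error.
#' @return A raw-state [quant_matrix()].
#' @export
read_quant_matrix <- function(path,
                              orientation = c("proteins_as_rows", "samples_as_rows"),
                              missing_codes = c("", "NA", "NaN", "nan"),
                              nonpositive_missing = TRUE) {
  orientation <- match.arg(orientation)
  df <- readr::read_delim(
    path, delim = infer_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  if (ncol(df) < 2) abort("Matrix file needs an ID column plus at least one data column.")
  row_ids <- trimws(df[[1]])
  if (anyDuplicated(row_ids)) {
    dups <- unique(row_ids[duplicated(row_ids)])
    abort(paste0("Duplicate row identifiers in ", path, ": ", paste(dups, collapse = ", ")))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  cells <- trimws(cells)
  is_missing <- is.na(cells) | cells %in% missing_codes
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!is_missing & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(sprintf(
      "Non-numeric cell not in missing_codes at row '%s', column '%s': \"%s\"",
      row_ids[b[1]], colnames(cells)[b[2]], cells[b[1], b[2]]
    ))
  }
  num[is_missing] <- NA_real_
  if (any(!is.na(num) & num <= 0)) {
    if (nonpositive_missing) {
      num[!is.na(num) & num <= 0] <- NA_real_
    } else {
      abort("Non-positive intensity found with nonpositive_missing = FALSE.")
    }
  }
  rownames(num) <- row_ids
  colnames(num) <- colnames(cells)
  if (orientation == "proteins_as_rows") num <- t(num)
  quant_matrix(num, transform = "raw")
}

#' Write a quantification matrix
#'
#' Inverse of [read_quant_matrix()]: writes the wide dialect with missing
#' entries as blank cells. Reading the file back (with matching
#' `orientation`) round-trips values, mask and ordering.
#'
#' @param m A [quant_matrix()].
#' @param path Output path (`.csv` comma, otherwise tab).
#' @param orientation Which dimension to place on rows.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(m, path,
                               orientation = c("proteins_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  v <- m$values
  if (orientation == "proteins_as_rows") v <- t(v)
  df <- tibble::as_tibble(v, .name_repair = "minimal")
  df <- tibble::add_column(df, id = rownames(v), .before = 1)
  names(df)[1] <- if (orientation == "proteins_as_rows") "protein_id" else "sample_id"
  readr::write_delim(df, path, delim = infer_delim(path), na = "")
  invisible(path)
}

#' Log10-transform a raw-state quantification matrix
#'
#' Replaces every observed entry by its base-10 logarithm; the missingness
#' mask is unchanged. Entries that cannot be transformed (<= 0) must have
#' been marked missing at read time and are an error here. The documented
#' inverse is `10^x` on observed entries.
#'
#' @param m A raw-state [quant_matrix()].
#' @return A log10-state `quant_matrix`.
#' @export
log10_transform <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$transform != "raw") abort("Matrix is already log10-transformed.")
  v <- m$values
  if (any(!is.na(v) & v <= 0)) {
    abort("Observed entries <= 0 cannot be log10-transformed; mark them missing at read time.")
  }
  v[] <- log10(v)
  quant_matrix(v, transform = "log10")
}

#' Single-sample protein record
#'
#' One test sample as it comes out of a single search: a mapping from
#' protein IDs to log10 intensities for the proteins actually quantified in
#' that sample. This is the unit the adaptive classifier consumes; it never
#' carries imputed values.
#'
#' @param quantified Named numeric vector of log10 intensities, names =
#'   protein IDs (unique, finite values).
#' @param sample_id Identifier for the sample.
#' @return A `sample_record` object.
#' @export
sample_record <- function(quantified, sample_id) {
  if (length(quantified) == 0) abort("A sample record needs at least one quantified protein.")
  if (is.null(names(quantified)) || any(names(quantified) == "")) {
    abort("`quantified` must be a named numeric vector (protein IDs as names).")
  }
  if (anyDuplicated(names(quantified))) {
    dups <- unique(names(quantified)[duplicated(names(quantified))])
    abort(paste0("Duplicate protein IDs in sample record: ", paste(dups, collapse = ", ")))
  }
  if (any(!is.finite(quantified))) abort("All intensities in a sample record must be finite.")
  structure(list(sample_id = as.character(sample_id), quantified = quantified),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> %s: %d quantified proteins\n",
              x$sample_id, length(x$quantified)))
  invisible(x)
}

#' Read a per-sample protein table
#'
#' Reads a two-column delimited table (protein ID, raw intensity) as
#' produced by a single-sample search. Non-positive intensities are dropped
#' (the protein was not usefully quantified); the rest are
#' log10-transformed.
#'
#' @param path Path to a two-column delimited file with header.
#' @param sample_id Identifier; defaults to the file name without extension.
#' @return A [sample_record()].
#' @export
read_sample_record <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- readr::read_delim(
    path, delim = infer_delim(path),
    col_types = readr::cols(
      readr::col_character(), readr::col_double()
    ), progress = FALSE, show_col_types = FALSE
  )
  if (nrow(df) == 0) abort(paste0("Empty sample table: ", path))
  if (ncol(df) < 2) abort("Sample table must have two columns: protein ID, intensity.")
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate protein IDs in ", path, ": ", paste(dups, collapse = ", ")))
  }
  intens <- df[[2]]
  keep <- !is.na(intens) & intens > 0
  if (!any(keep)) abort(paste0("No positive intensities in ", path))
  quantified <- stats::setNames(log10(intens[keep]), ids[keep])
  sample_record(quantified, sample_id)
}

#' Extract one sample of a log10 matrix as a sample record
#'
#' Pulls a single row out of a log10-state matrix, keeping only its observed
#' entries — the representation a test sample has when it arrives as an
#' individual measurement.
#'
#' @param m A log10-state [quant_matrix()].
#' @param sample_id Which sample to extract.
#' @return A [sample_record()].
#' @export
as_sample_record <- function(m, sample_id) {
  stopifnot(inherits(m, "quant_matrix"))
  if (m$transform != "log10") abort("as_sample_record() expects a log10-state matrix.")
  if (!sample_id %in% rownames(m$values)) {
    abort(paste0("Unknown sample ID: ", sample_id))
  }
  x <- m$values[sample_id, ]
  x <- x[!is.na(x)]
  sample_record(x, sample_id)
}

#' Read a sample metadata table
#'
#' CSV/TSV with a header; must contain a `sample_id` column with one row per
#' sample. Remaining columns are class labels and covariates (age, sex,
#' site, ...).
#'
#' @param path Path to the metadata file.
#' @return A tibble keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  df <- readr::read_delim(path, delim = infer_delim(path),
                          progress = FALSE, show_col_types = FALSE)
  if (!"sample_id" %in% names(df)) abort("Metadata must contain a `sample_id` column.")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    dups <- unique(df$sample_id[duplicated(df$sample_id)])
    abort(paste0("Duplicate sample IDs in metadata: ", paste(dups, collapse = ", ")))
  }
  tibble::as_tibble(df)
}
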