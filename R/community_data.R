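#' Construct a validated abundance matrix
#'
#' The universal currency of the pipeline: a rectangular samples-by-species
#' table of non-negative counts or biomass (mg). Rows are samples, columns are
#' species (or species/caste columns prior to biomass conversion).
#'
#' @param x numeric matrix with unique row names (sample ids) and unique
#'   column names (species ids).
#' @param value_kind `"count"` (integral values) or `"biomass"` (mg).
#' @return an `abund_matrix`: the matrix with a `value_kind` attribute.
#' @examples
#' m <- abundance_matrix(rbind(s1 = c(a = 3, b = 0), s2 = c(a = 0, b = 1)))
#' value_kind(m)
#' @export
abundance_matrix <- function(x, value_kind = c("count", "biomass")) {
  value_kind <- match.arg(value_kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("abundance matrix needs sample (row) and species (column) names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate species ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  }
  if (anyNA(x)) stop("abundance matrix contains missing values")
  if (any(x < 0)) stop("abundance matrix contains negative values")
  if (value_kind == "count" && any(abs(x - round(x)) > 1e-8)) {
    bad <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integral count at sample '%s', species '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  structure(x, value_kind = value_kind, class = c("abund_matrix", class(x)))
}

#' @rdname abundance_matrix
#' @export
value_kind <- function(x) {
  vk <- attr(x, "value_kind")
  if (is.null(vk)) "count" else vk
}

# Keep class/attribute through subsetting whenever the result is a matrix.
#' @export
`[.abund_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out)) {
    structure(out, value_kind = value_kind(x),
              class = c("abund_matrix", "matrix", "array"))
  } else {
    out
  }
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix (%s): %d samples x %d species\n",
              value_kind(x), nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a samples-by-species abundance table from CSV
#'
#' Expects a header row of species ids and a first column of sample ids.
#' Values must be non-negative; counts must be integral. Samples whose total
#' abundance is zero are rejected rather than dropped: an empty pitfall-trap
#' plot is suspect and should be dealt with explicitly upstream.
#'
#' @param path CSV file path.
#' @param value_kind `"count"` or `"biomass"`.
#' @return an [abundance_matrix()].
#' @export
read_abundance_table <- function(path, value_kind = c("count", "biomass")) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance CSV needs a sample-id column plus species columns")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        row <- which(is.na(vn))[1]
        stop(sprintf("non-numeric value at row %d (sample '%s'), column '%s'",
                     row, ids[row], names(body)[j]))
      }
      body[[j]] <- vn
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  colnames(m) <- names(df)[-1]  # as.matrix mangles duplicated headers
  m <- abundance_matrix(m, value_kind)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("samples with zero total abundance: ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  }
  m
}

#' Write an abundance matrix to CSV
#'
#' Inverse of [read_abundance_table()]; the first column is `sample_id`.
#'
#' @param matrix an [abundance_matrix()].
#' @param path output file.
#' @export
write_abundance_table <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix),
                   as.data.frame(unclass(matrix), check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert abundances to per-sample relative abundances
#'
#' Divides each sample row by its total so rows sum to one. Proportions are
#' always recomputed from the current (possibly pooled) matrix: pooling
#' conserves mass, not proportions.
#'
#' @param matrix an [abundance_matrix()] (counts or biomass).
#' @return matrix of proportions with class `rel_abund_matrix`.
#' @examples
#' m <- abundance_matrix(rbind(s1 = c(a = 3, b = 1)))
#' to_relative(m)  # 0.75, 0.25
#' @export
to_relative <- function(matrix) {
  tot <- rowSums(matrix)
  if (any(tot <= 0)) {
    stop("cannot form relative abundances; zero-total sample(s): ",
         paste(rownames(matrix)[tot <= 0], collapse = ", "))
  }
  p <- unclass(matrix) / tot
  structure(p, class = c("rel_abund_matrix", "matrix", "array"))
}

#' Drop species never observed in any sample
#'
#' Removes all-zero species columns; the sample axis and every row total are
#' unchanged. Idempotent.
#'
#' @param matrix an [abundance_matrix()].
#' @return the matrix without empty species columns.
#' @export
drop_empty_species <- function(matrix) {
  keep <- colSums(matrix) > 0
  matrix[, keep, drop = FALSE]
}

#' Read per-sample metadata (habitat, block, coordinates, year)
#'
#' @param path CSV with columns `sample_id`, `habitat` (one of `oil_palm`,
#'   `forest`), `block`, `latitude`, `longitude`, `year`.
#' @param matrix optional abundance matrix; if given, every sample must have
#'   exactly one metadata record.
#' @return data frame of metadata.
#' @export
read_sample_metadata <- function(path, matrix = NULL) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md, matrix)
}

#' @rdname read_sample_metadata
#' @param metadata a metadata data frame to validate in place.
#' @export
validate_metadata <- function(metadata, matrix = NULL) {
  need <- c("sample_id", "habitat", "block", "latitude", "longitude", "year")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  bad <- setdiff(metadata$habitat, c("oil_palm", "forest"))
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  if (!all(is.finite(metadata$latitude)) || !all(is.finite(metadata$longitude))) {
    stop("metadata coordinates must be finite")
  }
  if (!is.null(matrix)) {
    missing_md <- setdiff(rownames(matrix), metadata$sample_id)
    if (length(missing_md)) {
      stop("samples without metadata: ", paste(missing_md, collapse = ", "))
    }
  }
  metadata
}

#' Read species trait table (subfamily, caste, body dimension, dry weights)
#'
#' One row per species-caste combination. `dry_weights_mg` holds the weights
#' of individual oven-dried specimens joined by `;` (possibly empty); it is
#' parsed into a list column.
#'
#' @param path CSV with columns `species_id`, `subfamily`, `caste`
#'   (`major`/`minor`/`none`), `dimension_type`, `dimension_mm`,
#'   `dry_weights_mg`.
#' @return data frame with `dry_weights_mg` as a list of numeric vectors.
#' @export
read_species_traits <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "subfamily", "caste", "dimension_type",
            "dimension_mm", "dry_weights_mg")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("traits table lacks column(s): ", paste(miss, collapse = ", "))
  tr$dry_weights_mg <- lapply(as.character(tr$dry_weights_mg), function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  validate_traits(tr)
}

#' @rdname read_species_traits
#' @param traits a traits data frame (with list-column `dry_weights_mg`).
#' @export
validate_traits <- function(traits) {
  bad_caste <- setdiff(traits$caste, c("major", "minor", "none"))
  if (length(bad_caste)) stop("unknown caste label(s): ", paste(bad_caste, collapse = ", "))
  if (anyDuplicated(paste(traits$species_id, traits$caste))) {
    stop("duplicate species_id x caste rows in traits")
  }
  dm <- traits$dimension_mm
  if (any(!is.na(dm) & dm <= 0)) stop("dimension_mm must be positive when present")
  w <- unlist(traits$dry_weights_mg)
  if (length(w) && any(w <= 0)) stop("dry weights must be positive")
  traits
}

#' Write species traits to CSV (dry weights joined by ';')
#' @param traits traits data frame as from [read_species_traits()].
#' @param path output file.
#' @export
write_species_traits <- function(traits, path) {
  out <- traits
  out$dry_weights_mg <- vapply(traits$dry_weights_mg, function(w) {
    paste(format(w, digits = 12, trim = TRUE, scientific = FALSE), collapse = ";")
  }, character(1))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
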