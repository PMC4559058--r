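#' Mean measured dry weight of a species-caste
#'
#' The arithmetic mean of oven-dried specimen weights, accepted only when at
#' least three specimens were weighed; with fewer the species must be routed
#' through the allometric regression instead.
#'
#' @param traits traits data frame (see [read_species_traits()]).
#' @param species_id species to look up.
#' @param caste caste (`"major"`, `"minor"`, `"none"`).
#' @param min_specimens minimum specimen count (default 3).
#' @return one-row data frame (`species_id`, `caste`, `mean_weight_mg`,
#'   `source = "measured"`) or `NULL` when too few specimens.
#' @export
mean_measured_weight <- function(traits, species_id, caste = "none",
                                 min_specimens = 3) {
  i <- which(traits$species_id == species_id & traits$caste == caste)
  if (!length(i)) return(NULL)
  w <- traits$dry_weights_mg[[i[1]]]
  if (length(w) < min_specimens) return(NULL)
  data.frame(species_id = species_id, caste = caste,
             mean_weight_mg = mean(w), source = "measured",
             stringsAsFactors = FALSE)
}

#' Subfamily-to-body-dimension routing for the allometric models
#'
#' Head length for Dolichoderinae, Formicinae and Pseudomyrmecinae; tibia
#' length for Ponerinae; pronotum width for Myrmicinae. Subfamilies outside
#' the mapping fall back to a pooled all-species model.
#'
#' @param subfamily character vector of subfamily names.
#' @return character vector of dimension types (`"head_length"`,
#'   `"tibia_length"`, `"pronotum_width"`, or `"pooled"`).
#' @export
dimension_for_subfamily <- function(subfamily) {
  map <- c(Dolichoderinae = "head_length", Formicinae = "head_length",
           Pseudomyrmecinae = "head_length", Ponerinae = "tibia_length",
           Myrmicinae = "pronotum_width")
  out <- unname(map[subfamily])
  out[is.na(out)] <- "pooled"
  out
}

#' Fit allometric weight-dimension regressions
#'
#' Straight-line least squares of log mean dry weight (mg) on log body
#' dimension (mm), one model per dimension type, giving the power law
#' \eqn{W = e^{a} L^{b}}. Species with measured mean weights supply the
#' points; a pooled model over all weighed species backs up subfamilies with
#' no dimension-specific mapping.
#'
#' @param traits traits data frame.
#' @param min_specimens specimens needed for a measured mean (default 3).
#' @return list of `allometry_model` objects keyed by dimension type (always
#'   including `"pooled"`); each holds `intercept`, `slope`, `n_points`,
#'   `sigma2` (residual variance).
#' @export
fit_allometry <- function(traits, min_specimens = 3) {
  measured <- traits[vapply(traits$dry_weights_mg, length, 0L) >= min_specimens &
                       !is.na(traits$dimension_mm), , drop = FALSE]
  if (!nrow(measured)) stop("no species with measured weights and dimensions")
  measured$mean_w <- vapply(measured$dry_weights_mg, mean, 0)
  fit_one <- function(df, label) {
    if (length(unique(df$dimension_mm)) < 2) {
      stop(sprintf("allometry group '%s' has fewer than 2 distinct dimensions", label))
    }
    fit <- stats::lm(log(mean_w) ~ log(dimension_mm), data = df)
    structure(list(dimension_type = label,
                   intercept = unname(stats::coef(fit)[1]),
                   slope = unname(stats::coef(fit)[2]),
                   n_points = nrow(df),
                   sigma2 = stats::sigma(fit)^2),
              class = "allometry_model")
  }
  groups <- split(measured, measured$dimension_type)
  models <- lapply(names(groups), function(g) fit_one(groups[[g]], g))
  names(models) <- names(groups)
  models$pooled <- fit_one(measured, "pooled")
  models
}

#' Predict mean dry weight from a body dimension
#'
#' @param model an `allometry_model` from [fit_allometry()].
#' @param dimension_mm positive body dimension(s) in mm.
#' @return predicted mean dry weight(s) in mg (always positive).
#' @export
predict_weight <- function(model, dimension_mm) {
  if (any(dimension_mm <= 0)) stop("dimension must be positive")
  exp(model$intercept + model$slope * log(dimension_mm))
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf("allometry [%s]: log W = %.4f + %.4f log L  (n = %d)\n",
              x$dimension_type, x$intercept, x$slope, x$n_points))
  invisible(x)
}

#' Resolve a mean weight for every species-caste in the traits table
#'
#' Measured means where at least `min_specimens` specimens exist, otherwise
#' the allometric prediction for the subfamily's body dimension (pooled model
#' for unmapped subfamilies). Species lacking both weights and a dimension
#' are reported together in one error.
#'
#' @param traits traits data frame.
#' @param models allometry models from [fit_allometry()] (fitted on the fly
#'   when `NULL`).
#' @param min_specimens specimens needed for a measured mean.
#' @return data frame (`species_id`, `caste`, `mean_weight_mg`, `source`).
#' @export
species_weights <- function(traits, models = NULL, min_specimens = 3) {
  if (is.null(models)) models <- fit_allometry(traits, min_specimens)
  rows <- lapply(seq_len(nrow(traits)), function(i) {
    m <- mean_measured_weight(traits, traits$species_id[i], traits$caste[i],
                              min_specimens)
    if (!is.null(m)) return(m)
    dim_mm <- traits$dimension_mm[i]
    if (is.na(dim_mm)) {
      return(data.frame(species_id = traits$species_id[i],
                        caste = traits$caste[i],
                        mean_weight_mg = NA_real_, source = "unresolvable",
                        stringsAsFactors = FALSE))
    }
    dtype <- dimension_for_subfamily(traits$subfamily[i])
    model <- models[[dtype]]
    if (is.null(model)) model <- models$pooled
    data.frame(species_id = traits$species_id[i], caste = traits$caste[i],
               mean_weight_mg = predict_weight(model, dim_mm),
               source = "predicted", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$source == "unresolvable")) {
    bad <- out[out$source == "unresolvable", ]
    stop("species with neither measured weight nor body dimension: ",
         paste(paste(bad$species_id, bad$caste, sep = "/"), collapse = ", "))
  }
  out
}

#' Convert a count matrix to biomass (mg)
#'
#' Each cell becomes count x mean individual weight. Columns of the count
#' matrix are either plain species ids (caste `"none"`) or `species_caste`
#' for caste-split counts; after conversion the castes of a species are
#' summed into a single species column, so the total biomass equals
#' \eqn{\sum \text{count} \times \text{weight}} exactly.
#'
#' @param counts a count [abundance_matrix()].
#' @param weights weight table from [species_weights()] (computed from
#'   `traits` when `NULL`).
#' @param traits traits table, needed when `weights` is `NULL`.
#' @param sep separator between species id and caste in column names.
#' @return a biomass [abundance_matrix()] with one column per species.
#' @examples
#' cts <- abundance_matrix(rbind(s1 = c(spA_major = 2, spA_minor = 10)))
#' w <- data.frame(species_id = "spA", caste = c("major", "minor"),
#'                 mean_weight_mg = c(1.0, 0.2), source = "measured")
#' counts_to_biomass(cts, w)  # spA = 4 mg
#' @export
counts_to_biomass <- function(counts, weights = NULL, traits = NULL,
                              sep = "_") {
  if (value_kind(counts) != "count") stop("input must be a count matrix")
  if (is.null(weights)) {
    if (is.null(traits)) stop("provide either weights or traits")
    weights <- species_weights(traits)
  }
  cols <- colnames(counts)
  key_w <- ifelse(weights$caste == "none", weights$species_id,
                  paste(weights$species_id, weights$caste, sep = sep))
  idx <- match(cols, key_w)
  if (anyNA(idx)) {
    stop("no weight available for column(s): ",
         paste(cols[is.na(idx)], collapse = ", "))
  }
  w <- weights$mean_weight_mg[idx]
  sp <- weights$species_id[idx]
  bm <- sweep(unclass(counts), 2, w, `*`)
  # collapse caste columns of one species
  species_levels <- unique(sp)
  out <- vapply(species_levels, function(s) {
    rowSums(bm[, sp == s, drop = FALSE])
  }, numeric(nrow(bm)))
  out <- matrix(out, nrow = nrow(bm),
                dimnames = list(rownames(counts), species_levels))
  abundance_matrix(out, "biomass")
}

#' Collapse caste-split count columns to one column per species
#'
#' @param counts a count [abundance_matrix()] with `species_caste` columns.
#' @param sep separator used in column names.
#' @return count matrix with one column per species.
#' @export
collapse_castes <- function(counts, sep = "_") {
  sp <- sub(paste0(sep, "(major|minor)$"), "", colnames(counts))
  species_levels <- unique(sp)
  out <- vapply(species_levels, function(s) {
    rowSums(unclass(counts)[, sp == s, drop = FALSE])
  }, numeric(nrow(counts)))
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), species_levels))
  abundance_matrix(out, value_kind(counts))
}

#' Species mapping of (possibly caste-split) matrix columns
#' @param cols column names of a count matrix.
#' @param sep separator used between species and caste.
#' @return character vector of species ids, one per column.
#' @export
column_species <- function(cols, sep = "_") {
  sub(paste0(sep, "(major|minor)$"), "", cols)
}
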