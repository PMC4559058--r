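#' Configuration for a full multi-grain beta-diversity analysis
#'
#' @param truth a [synthetic_truth()] to simulate from, or `NULL` when
#'   reading data from files.
#' @param counts_path,metadata_path,traits_path input CSVs (used when
#'   `truth` is `NULL`).
#' @param q diversity orders to analyse (default 0, 1, 2).
#' @param caps grain distance caps in km (level 2, level 3).
#' @param B_pairwise bootstrap iterations for mean pairwise similarities
#'   (default 500).
#' @param B_multi bootstrap iterations for multi-assemblage overlap and mean
#'   alpha (default 1000).
#' @param alpha FDR level for the Z-test families.
#' @param currency `"biomass"` (counts converted via the allometry-backed
#'   weights, the default) or `"count"` (raw counts, mainly for testing).
#' @param omit_singletons also run the singleton-omitted repeat analysis.
#' @param scheme bootstrap scheme: `"auto"` picks individual resampling at
#'   grain 1 (where units are single plots and unit resampling is
#'   degenerate) and unit resampling at pooled grains.
#' @param seed master seed; every bootstrap seed is derived from it.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(truth = NULL, counts_path = NULL,
                            metadata_path = NULL, traits_path = NULL,
                            q = c(0, 1, 2), caps = c(grain2 = 5, grain3 = 45),
                            B_pairwise = 500, B_multi = 1000, alpha = 0.05,
                            currency = c("biomass", "count"),
                            omit_singletons = TRUE,
                            scheme = c("auto", "resample_units",
                                       "resample_individuals"),
                            seed = 1L) {
  if (any(q < 0)) stop("diversity orders must be non-negative")
  if (B_pairwise < 2 || B_multi < 2) stop("bootstrap iteration counts must be >= 2")
  structure(list(truth = truth, counts_path = counts_path,
                 metadata_path = metadata_path, traits_path = traits_path,
                 q = q, caps = caps, B_pairwise = B_pairwise,
                 B_multi = B_multi, alpha = alpha,
                 currency = match.arg(currency),
                 omit_singletons = omit_singletons,
                 scheme = match.arg(scheme), seed = as.integer(seed)),
            class = "analysis_config")
}

#' Shared-species summary of a two-habitat dataset
#'
#' Counts the species with positive total abundance in each habitat, their
#' intersection and union (inclusion-exclusion), the percentage of each
#' habitat's species exclusive to it (one decimal), and per-habitat totals.
#'
#' @param matrix abundance matrix with one column per species.
#' @param metadata metadata with `sample_id`, `habitat`.
#' @return list of class `study_summary`.
#' @export
shared_species_summary <- function(matrix, metadata) {
  hab <- metadata$habitat[match(rownames(matrix), metadata$sample_id)]
  if (anyNA(hab)) stop("metadata does not cover all samples")
  if (!all(c("oil_palm", "forest") %in% hab)) {
    stop("both habitats must be present")
  }
  present <- function(h) colSums(matrix[hab == h, , drop = FALSE]) > 0
  in_op <- present("oil_palm"); in_fo <- present("forest")
  S_op <- sum(in_op); S_fo <- sum(in_fo)
  shared <- sum(in_op & in_fo)
  structure(list(
    species_oil_palm = S_op,
    species_forest = S_fo,
    shared_species = shared,
    union_species = S_op + S_fo - shared,
    exclusive_pct_oil_palm = round(100 * (S_op - shared) / S_op, 1),
    exclusive_pct_forest = round(100 * (S_fo - shared) / S_fo, 1),
    total_oil_palm = sum(matrix[hab == "oil_palm", , drop = FALSE]),
    total_forest = sum(matrix[hab == "forest", , drop = FALSE]),
    value_kind = value_kind(matrix)), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf(paste0("oil palm: %d species (total %s %.1f), forest: %d species ",
                     "(total %s %.1f)\n%d shared; union %d; exclusive: ",
                     "oil palm %.1f%%, forest %.1f%%\n"),
              x$species_oil_palm, x$value_kind, x$total_oil_palm,
              x$species_forest, x$value_kind, x$total_forest,
              x$shared_species, x$union_species,
              x$exclusive_pct_oil_palm, x$exclusive_pct_forest))
  invisible(x)
}

# weight lookup aligned to caste-split count columns; returns the column
# weight vector and the column -> species indicator matrix
.column_conversion <- function(cols, weights, currency) {
  sp <- column_species(cols)
  key_w <- ifelse(weights$caste == "none", weights$species_id,
                  paste(weights$species_id, weights$caste, sep = "_"))
  species_levels <- unique(sp)
  Ind <- matrix(0, length(cols), length(species_levels),
                dimnames = list(cols, species_levels))
  Ind[cbind(seq_along(cols), match(sp, species_levels))] <- 1
  if (currency == "biomass") {
    idx <- match(cols, key_w)
    if (anyNA(idx)) stop("no weight for column(s): ",
                         paste(cols[is.na(idx)], collapse = ", "))
    w <- weights$mean_weight_mg[idx]
  } else {
    w <- rep(1, length(cols))
  }
  list(w = w, Ind = Ind)
}

# counts (units x caste-columns) -> analysis currency (units x species)
.to_currency <- function(m, conv) {
  out <- (unclass(m) * rep(conv$w, each = nrow(m))) %*% conv$Ind
  out
}

#' Run the full multi-grain beta-diversity analysis
#'
#' Orchestrates simulate/load, biomass conversion, grain pooling, alpha
#' diversity, between-habitat pairwise similarity, multi-assemblage overlap
#' with bootstrap SEs, Z tests with FDR control, the singleton-omitted
#' repeat, and the rank-biomass tables.
#'
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, every report table is also
#'   written there as CSV.
#' @return list of class `analysis_report` with elements `summary`,
#'   `alpha_table`, `pairwise_table`, `pairwise_contrasts`, `overlap_table`,
#'   `overlap_grain_contrasts`, `overlap_habitat_contrasts`,
#'   `singleton_omitted` (same shape, or `NULL`), `rank_biomass`,
#'   `hierarchy`, `run_log`.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$truth)) {
    land <- generate_landscape(config$truth)
    counts <- land$counts; metadata <- land$metadata; traits <- land$traits
  } else {
    counts <- read_abundance_table(config$counts_path, "count")
    metadata <- read_sample_metadata(config$metadata_path, counts)
    traits <- read_species_traits(config$traits_path)
  }
  counts <- drop_empty_species(counts)
  weights <- if (config$currency == "biomass") species_weights(traits) else NULL
  species_counts <- collapse_castes(counts)
  summary <- shared_species_summary(species_counts, metadata)

  hier <- build_hierarchy(counts, metadata, caps = config$caps)
  singles <- sum(colSums(species_counts) == 1)

  core <- .analysis_core(counts, hier, metadata, weights, config, tag = "all")
  singleton_omitted <- NULL
  if (config$omit_singletons) {
    cts2 <- remove_singletons(counts, column_species(colnames(counts)))
    hier2 <- build_hierarchy(cts2, metadata, caps = config$caps)
    singleton_omitted <- .analysis_core(cts2, hier2, metadata, weights,
                                        config, tag = "no_singletons")
  }

  run_log <- list(seed = config$seed, currency = config$currency,
                  scheme = config$scheme, n_singleton_species = singles,
                  omitted = lapply(hier, `[[`, "omitted"),
                  B_pairwise = config$B_pairwise, B_multi = config$B_multi,
                  alpha = config$alpha)
  report <- structure(c(list(summary = summary), core,
                        list(singleton_omitted = singleton_omitted,
                             hierarchy = hier, run_log = run_log)),
                      class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# the grain x q x habitat analysis shared by the main and the
# singleton-omitted rounds
.analysis_core <- function(counts, hier, metadata, weights, config, tag) {
  conv <- .column_conversion(colnames(counts), weights, config$currency)
  seed_base <- config$seed + if (tag == "all") 0L else 100000L
  levels <- names(hier)
  alpha_rows <- list(); pair_rows <- list(); over_rows <- list()
  rank_tabs <- list()
  sid <- 0L
  next_seed <- function() { sid <<- sid + 1L; seed_base + sid }

  for (lv in levels) {
    m_cts <- hier[[lv]]$matrix
    md <- hier[[lv]]$metadata
    m_cur <- abundance_matrix(.to_currency(m_cts, conv),
                              if (config$currency == "biomass") "biomass" else "count")
    hab <- md$habitat[match(rownames(m_cur), md$sample_id)]
    grain_no <- as.integer(sub("grain", "", lv))
    scheme_lv <- if (config$scheme != "auto") config$scheme else
      if (grain_no == 1) "resample_individuals" else "resample_units"

    if (config$currency == "biomass") {
      rank_tabs[[lv]] <- cbind(grain = grain_no, top_biomass_ranks(m_cur, 20))
    }

    for (qv in config$q) {
      # (a) mean per-unit alpha by habitat
      for (h in unique(hab)) {
        ma <- mean_alpha(m_cur[hab == h, , drop = FALSE], qv,
                         B = config$B_multi, seed = next_seed())
        alpha_rows[[length(alpha_rows) + 1L]] <-
          data.frame(grain = grain_no, habitat = h, q = qv,
                     mean_alpha = ma$mean, se = ma$se, n = ma$n)
      }
      # (b) mean between-habitat pairwise similarity
      if (all(c("oil_palm", "forest") %in% hab)) {
        mp <- mean_pairwise_between(m_cur, md, qv, B = config$B_pairwise,
                                    seed = next_seed())
        pair_rows[[length(pair_rows) + 1L]] <-
          data.frame(grain = grain_no, q = qv, mean_similarity = mp$mean,
                     se = mp$se, n_pairs = mp$n_pairs)
      }
      # (c) multi-assemblage overlap per habitat
      for (h in unique(hab)) {
        rows_h <- which(hab == h)
        if (length(rows_h) < 2) next
        cts_h <- m_cts[rows_h, , drop = FALSE]
        boot <- bootstrap_statistic(
          cts_h, B = config$B_multi, seed = next_seed(), scheme = scheme_lv,
          statistic = function(m, idx) {
            overlap_CqN(.to_currency(m, conv), qv)$CqN
          })
        over_rows[[length(over_rows) + 1L]] <-
          data.frame(grain = grain_no, habitat = h, q = qv,
                     N = length(rows_h), CqN = boot$estimate,
                     beta = 1 - boot$estimate, se = boot$se,
                     scheme = scheme_lv)
      }
    }
  }
  alpha_table <- do.call(rbind, alpha_rows)
  pairwise_table <- do.call(rbind, pair_rows)
  overlap_table <- do.call(rbind, over_rows)

  # between-grain Z/FDR families: pairwise similarities (one family per q)
  pairwise_contrasts <- NULL
  if (!is.null(pairwise_table) && length(unique(pairwise_table$grain)) >= 2) {
    pairwise_contrasts <- do.call(rbind, lapply(unique(pairwise_table$q), function(qv) {
      sub <- pairwise_table[pairwise_table$q == qv, ]
      est <- data.frame(label = paste0("grain", sub$grain),
                        estimate = sub$mean_similarity, se = sub$se)
      cbind(q = qv, compare_estimates(est, alpha = config$alpha))
    }))
  }
  # overlap: between-grain per (q, habitat); between-habitat per q
  overlap_grain_contrasts <- NULL
  overlap_habitat_contrasts <- NULL
  if (!is.null(overlap_table)) {
    combos <- unique(overlap_table[, c("q", "habitat")])
    overlap_grain_contrasts <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      sub <- overlap_table[overlap_table$q == combos$q[i] &
                             overlap_table$habitat == combos$habitat[i], ]
      if (nrow(sub) < 2) return(NULL)
      est <- data.frame(label = paste0("grain", sub$grain),
                        estimate = sub$beta, se = sub$se)
      cbind(q = combos$q[i], habitat = combos$habitat[i],
            compare_estimates(est, alpha = config$alpha))
    }))
    overlap_habitat_contrasts <- do.call(rbind, lapply(unique(overlap_table$q), function(qv) {
      sub <- overlap_table[overlap_table$q == qv, ]
      grains <- sort(unique(sub$grain))
      rows <- lapply(grains, function(g) {
        a <- sub[sub$grain == g & sub$habitat == "oil_palm", ]
        b <- sub[sub$grain == g & sub$habitat == "forest", ]
        if (nrow(a) != 1 || nrow(b) != 1) return(NULL)
        cbind(grain = g, z_test_safe(a$beta, a$se, b$beta, b$se,
                                     labels = c("oil_palm", "forest")))
      })
      rows <- do.call(rbind, rows)
      if (is.null(rows)) return(NULL)
      cbind(q = qv, fdr_augment(rows, config$alpha))
    }))
  }
  list(alpha_table = alpha_table,
       pairwise_table = pairwise_table,
       pairwise_contrasts = pairwise_contrasts,
       overlap_table = overlap_table,
       overlap_grain_contrasts = overlap_grain_contrasts,
       overlap_habitat_contrasts = overlap_habitat_contrasts,
       rank_biomass = if (length(rank_tabs)) do.call(rbind, rank_tabs) else NULL)
}

#' Write an analysis report's tables to CSV files
#'
#' @param report an `analysis_report` from [run_full_analysis()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  put <- function(x, name) {
    if (!is.null(x)) utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  }
  put(as.data.frame(unclass(report$summary)), "summary.csv")
  put(report$alpha_table, "alpha.csv")
  put(report$pairwise_table, "pairwise.csv")
  put(report$pairwise_contrasts, "pairwise_contrasts.csv")
  put(report$overlap_table, "overlap.csv")
  put(report$overlap_grain_contrasts, "overlap_grain_contrasts.csv")
  put(report$overlap_habitat_contrasts, "overlap_habitat_contrasts.csv")
  put(report$rank_biomass, "rank_biomass.csv")
  so <- report$singleton_omitted
  if (!is.null(so)) {
    put(so$pairwise_table, "pairwise_no_singletons.csv")
    put(so$overlap_table, "overlap_no_singletons.csv")
    put(so$overlap_grain_contrasts, "overlap_grain_contrasts_no_singletons.csv")
  }
  write_hierarchy(report$hierarchy, file.path(dir, "hierarchy.csv"))
  log_df <- data.frame(key = c("seed", "currency", "scheme",
                               "n_singleton_species", "B_pairwise", "B_multi",
                               "alpha",
                               paste0("omitted_", names(report$run_log$omitted))),
                       value = c(report$run_log$seed, report$run_log$currency,
                                 report$run_log$scheme,
                                 report$run_log$n_singleton_species,
                                 report$run_log$B_pairwise,
                                 report$run_log$B_multi, report$run_log$alpha,
                                 vapply(report$run_log$omitted, function(o) {
                                   paste(o, collapse = ";")
                                 }, character(1))))
  utils::write.csv(log_df, file.path(dir, "run_log.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  print(x$summary)
  cat("\nMulti-assemblage beta (1 - CqN) by habitat, grain, q:\n")
  print(x$overlap_table, row.names = FALSE)
  invisible(x)
}
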