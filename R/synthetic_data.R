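#' Ground-truth parameters for a synthetic two-habitat landscape
#'
#' Defines everything the generator needs: species-pool sizes and their
#' overlap, the rank-abundance model, plot counts and sampling depth, the
#' spatial layout (pairs of plots in tight clusters, pair-clusters far
#' apart) and the per-subfamily body-mass model. Defaults emulate the
#' motivating field design: 105 oil-palm and 181 forest species with 63
#' shared, 26 + 21 plots, plot pairs 1-4 km apart and pair-clusters tens of
#' km apart.
#'
#' @param n_species_oil_palm,n_species_forest species-pool sizes.
#' @param n_shared number of species common to both pools
#'   (`<= min` of the pool sizes).
#' @param abundance_model list: `model = "log_series"` with parameter `x`
#'   (rank-abundance decay, 0 < x < 1), or `model = "lognormal"` with
#'   `sdlog`.
#' @param n_plots named vector: plots per habitat.
#' @param individuals_per_plot expected pitfall catch per plot (>= 1).
#' @param spatial_layout list of distances in km: `within_pair_km` (plot
#'   separation inside a pair), `pair_gap_km` (separation of the two pairs
#'   of a grain-3 cluster), `cluster_gap_km` (separation between clusters),
#'   `jitter_km` (uniform jitter on plot positions).
#' @param body_mass_model per-subfamily power-law coefficients `a`, `b`
#'   (dry weight mg = a * dimension_mm ^ b) plus lognormal noise `sdlog`.
#' @param prop_dimorphic fraction of species with distinct major/minor
#'   castes.
#' @param prop_weighed fraction of species-caste rows given >= 3 measured
#'   dry weights (the rest exercise the allometric prediction).
#' @param seed integer seed; all generator randomness flows through it.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_species_oil_palm = 105,
                            n_species_forest = 181,
                            n_shared = 63,
                            abundance_model = list(model = "log_series", x = 0.98),
                            n_plots = c(oil_palm = 26, forest = 21),
                            individuals_per_plot = 550,
                            spatial_layout = list(within_pair_km = 2,
                                                  pair_gap_km = 8,
                                                  cluster_gap_km = 60,
                                                  jitter_km = 0.5),
                            body_mass_model = NULL,
                            prop_dimorphic = 0.08,
                            prop_weighed = 0.85,
                            seed = 1L) {
  if (n_shared > min(n_species_oil_palm, n_species_forest)) {
    stop("n_shared exceeds the smaller species pool")
  }
  if (individuals_per_plot < 1) stop("individuals_per_plot must be >= 1")
  if (is.null(body_mass_model)) {
    body_mass_model <- list(
      Dolichoderinae  = list(a = 0.45, b = 2.5),
      Formicinae      = list(a = 0.55, b = 2.6),
      Pseudomyrmecinae = list(a = 0.40, b = 2.4),
      Ponerinae       = list(a = 0.30, b = 2.8),
      Myrmicinae      = list(a = 0.60, b = 2.5),
      other           = list(a = 0.50, b = 2.5),
      sdlog = 0.15)
  }
  structure(list(n_species_oil_palm = n_species_oil_palm,
                 n_species_forest = n_species_forest,
                 n_shared = n_shared,
                 abundance_model = abundance_model,
                 n_plots = n_plots,
                 individuals_per_plot = individuals_per_plot,
                 spatial_layout = spatial_layout,
                 body_mass_model = body_mass_model,
                 prop_dimorphic = prop_dimorphic,
                 prop_weighed = prop_weighed,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic landscape truth: %d + %d species (%d shared), ",
                     "%d + %d plots, %d individuals/plot, seed %d\n"),
              x$n_species_oil_palm, x$n_species_forest, x$n_shared,
              x$n_plots[["oil_palm"]], x$n_plots[["forest"]],
              x$individuals_per_plot, x$seed))
  invisible(x)
}

# expected relative abundances for S ranked species
.rank_abundances <- function(S, model) {
  p <- switch(model$model,
    log_series = { i <- seq_len(S); model$x^i / i },
    lognormal  = stats::qlnorm(stats::ppoints(S), 0, model$sdlog)[S:1],
    stop("unknown abundance model: ", model$model))
  p / sum(p)
}

#' Generate the two habitat species pools
#'
#' Draws the union species list, assigns each species a subfamily and a body
#' dimension, and gives every species in a habitat an expected relative
#' abundance from the rank-abundance model, with ranks permuted
#' independently per habitat so the dominant species of the two habitats
#' differ.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `pool_oil_palm` and `pool_forest` (data frames
#'   `species_id`, `p`), and `species` (union table with `species_id`,
#'   `subfamily`, `dimension_type`, `dimension_mm`, `habitats`).
#' @export
generate_species_pools <- function(truth) {
  withr::with_seed(truth$seed, .generate_pools_impl(truth))
}

.generate_pools_impl <- function(truth) {
  A <- truth$n_species_oil_palm
  B <- truth$n_species_forest
  sh <- truth$n_shared
  U <- A + B - sh
  ids <- sprintf("sp%04d", seq_len(U))
  id_shared <- ids[seq_len(sh)]
  id_A_only <- ids[seq_len(A - sh) + sh]
  id_B_only <- ids[seq_len(B - sh) + A]
  pool_ids_A <- c(id_shared, id_A_only)
  pool_ids_B <- c(id_shared, id_B_only)

  subfams <- c("Dolichoderinae", "Formicinae", "Pseudomyrmecinae",
               "Ponerinae", "Myrmicinae", "Dorylinae", "Ectatomminae",
               "Proceratiinae", "Amblyoponinae", "Leptanillinae")
  sf <- sample(subfams, U, replace = TRUE,
               prob = c(0.10, 0.22, 0.03, 0.18, 0.37, 0.03, 0.03, 0.02, 0.01, 0.01))
  species <- data.frame(
    species_id = ids,
    subfamily = sf,
    dimension_type = dimension_for_subfamily(sf),
    dimension_mm = stats::rlnorm(U, meanlog = log(0.9), sdlog = 0.35),
    habitats = c(rep("both", sh), rep("oil_palm", A - sh), rep("forest", B - sh)),
    stringsAsFactors = FALSE)

  pA <- .rank_abundances(A, truth$abundance_model)
  pB <- .rank_abundances(B, truth$abundance_model)
  pool_oil_palm <- data.frame(species_id = pool_ids_A,
                              p = pA[sample.int(A)],
                              stringsAsFactors = FALSE)
  pool_forest <- data.frame(species_id = pool_ids_B,
                            p = pB[sample.int(B)],
                            stringsAsFactors = FALSE)
  list(pool_oil_palm = pool_oil_palm, pool_forest = pool_forest,
       species = species)
}

#' Multinomial pitfall sample from a species pool
#'
#' @param pool data frame with `species_id` and expected proportions `p`.
#' @param n_individuals catch size (>= 1).
#' @return named integer count vector over the pool's species.
#' @export
sample_plot <- function(pool, n_individuals) {
  if (!nrow(pool)) stop("cannot sample from an empty species pool")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  cts <- as.integer(stats::rmultinom(1, n_individuals, pool$p / sum(pool$p)))
  stats::setNames(cts, pool$species_id)
}

# lay out plots of one habitat: pairs inside far-apart clusters of two
# pairs; an odd plot is placed isolated (unpairable), an odd pair gets its
# own cluster (pairable at grain 2, not at grain 3)
.layout_habitat <- function(n_plots, layout, lat0, lon0) {
  km_lat <- 1 / 111.2
  km_lon <- 1 / (111.2 * cos(lat0 * pi / 180))
  n_pairs <- n_plots %/% 2
  odd_plot <- n_plots %% 2 == 1
  n_clusters <- ceiling(n_pairs / 2)
  pos <- matrix(NA_real_, n_plots, 2)  # lon, lat
  k <- 0L
  for (cl in seq_len(n_clusters)) {
    c_lon <- lon0 + (cl - 1) * layout$cluster_gap_km * km_lon
    pairs_here <- if (cl < n_clusters || n_pairs %% 2 == 0) 2L else 1L
    for (pr in seq_len(pairs_here)) {
      p_lat <- lat0 + (pr - 1) * layout$pair_gap_km * km_lat
      for (plot in 1:2) {
        k <- k + 1L
        jit <- stats::runif(2, -layout$jitter_km, layout$jitter_km)
        pos[k, ] <- c(c_lon + (plot - 1) * layout$within_pair_km * km_lon +
                        jit[1] * km_lon,
                      p_lat + jit[2] * km_lat)
      }
    }
  }
  if (odd_plot) {
    k <- k + 1L
    pos[k, ] <- c(lon0 - 25 * km_lon, lat0 - 25 * km_lat)
  }
  pos
}

#' Generate a full synthetic landscape
#'
#' Produces a grain-1 count matrix (caste-split columns for dimorphic
#' species), sample metadata whose spatial layout satisfies the grain
#' pairing rules, a species-trait table with measured dry weights for most
#' species, and the truth object for parameter-recovery tests. All
#' randomness derives from `truth$seed`; identical truths give identical
#' landscapes.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `counts` (an [abundance_matrix()]), `metadata`,
#'   `traits`, `pools` (from [generate_species_pools()]), and `truth`.
#' @export
generate_landscape <- function(truth) {
  withr::with_seed(truth$seed, {
    pools <- .generate_pools_impl(truth)
    species <- pools$species

    # which species are caste-dimorphic; split abundance majors:minors
    dimorphic <- stats::runif(nrow(species)) < truth$prop_dimorphic
    names(dimorphic) <- species$species_id
    col_of <- function(sp) {
      unlist(lapply(sp, function(s) {
        if (dimorphic[[s]]) paste(s, c("major", "minor"), sep = "_") else s
      }))
    }
    all_cols <- col_of(species$species_id)

    expand_pool <- function(pool) {
      rows <- lapply(seq_len(nrow(pool)), function(i) {
        s <- pool$species_id[i]
        if (dimorphic[[s]]) {
          data.frame(species_id = paste(s, c("major", "minor"), sep = "_"),
                     p = pool$p[i] * c(0.15, 0.85), stringsAsFactors = FALSE)
        } else {
          data.frame(species_id = s, p = pool$p[i], stringsAsFactors = FALSE)
        }
      })
      do.call(rbind, rows)
    }
    pool_of <- list(oil_palm = pools$pool_oil_palm,
                    forest = pools$pool_forest)

    # spatial layout per habitat (forest offset north so habitats are distinct)
    lay <- list(
      oil_palm = .layout_habitat(truth$n_plots[["oil_palm"]],
                                 truth$spatial_layout, 4.6, 116.2),
      forest = .layout_habitat(truth$n_plots[["forest"]],
                               truth$spatial_layout, 5.6, 116.5))

    mats <- list(); md <- list()
    for (hab in c("oil_palm", "forest")) {
      np <- truth$n_plots[[hab]]
      prefix <- if (hab == "oil_palm") "OP" else "FO"
      ids <- sprintf("%s%02d", prefix, seq_len(np))
      # assembly-history heterogeneity: every block permutes the habitat
      # pool's rank abundances independently, so dominant species differ
      # among blocks while pool membership stays fixed
      block_id <- (seq_len(np) - 1) %/% 4 + 1
      pool <- pool_of[[hab]]
      block_pools <- lapply(seq_len(max(block_id)), function(b) {
        p_perm <- pool$p[sample.int(nrow(pool))]
        expand_pool(data.frame(species_id = pool$species_id, p = p_perm,
                               stringsAsFactors = FALSE))
      })
      m <- t(vapply(seq_len(np), function(i) {
        v <- sample_plot(block_pools[[block_id[i]]], truth$individuals_per_plot)
        out <- stats::setNames(numeric(length(all_cols)), all_cols)
        out[names(v)] <- v
        out
      }, numeric(length(all_cols))))
      rownames(m) <- ids
      mats[[hab]] <- m
      md[[hab]] <- data.frame(
        sample_id = ids, habitat = hab,
        block = paste0(prefix, "_block", (seq_len(np) - 1) %/% 4 + 1),
        latitude = lay[[hab]][, 2], longitude = lay[[hab]][, 1],
        year = ifelse(seq_len(np) %% 2 == 0, 2012L, 2011L),
        stringsAsFactors = FALSE)
    }
    counts <- abundance_matrix(rbind(mats$oil_palm, mats$forest), "count")
    metadata <- rbind(md$oil_palm, md$forest)

    # traits: one row per species-caste; most weighed >= 3x, rest predicted
    bm <- truth$body_mass_model
    trait_rows <- lapply(seq_len(nrow(species)), function(i) {
      s <- species$species_id[i]
      castes <- if (dimorphic[[s]]) c("major", "minor") else "none"
      do.call(rbind, lapply(castes, function(cs) {
        dim_mm <- species$dimension_mm[i] *
          switch(cs, major = 1.6, minor = 0.85, none = 1)
        coefs <- bm[[species$subfamily[i]]]
        if (is.null(coefs)) coefs <- bm$other
        mu <- coefs$a * dim_mm^coefs$b
        n_w <- if (stats::runif(1) < truth$prop_weighed) {
          sample(3:5, 1)
        } else {
          sample(0:2, 1)
        }
        w <- mu * stats::rlnorm(n_w, 0, bm$sdlog)
        data.frame(species_id = s, subfamily = species$subfamily[i],
                   caste = cs, dimension_type = species$dimension_type[i],
                   dimension_mm = dim_mm,
                   dry_weights_mg = I(list(w)), stringsAsFactors = FALSE)
      }))
    })
    traits <- do.call(rbind, trait_rows)
    traits <- validate_traits(traits)

    list(counts = counts, metadata = metadata, traits = traits,
         pools = pools, truth = truth)
  })
}

#' Write a synthetic landscape to CSV files plus a truth sidecar
#'
#' @param landscape output of [generate_landscape()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "metadata.csv", "traits.csv",
                            "truth.json"))
  write_abundance_table(landscape$counts, paths[1])
  utils::write.csv(landscape$metadata, paths[2], row.names = FALSE)
  write_species_traits(landscape$traits, paths[3])
  truth <- landscape$truth
  truth$n_plots <- as.list(truth$n_plots)
  jsonlite::write_json(unclass(truth), paths[4], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
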