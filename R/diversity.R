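#' Hill number (effective number of species) of order q
#'
#' For a relative-abundance vector `p`, computes
#' \deqn{{}^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}}
#' with the Shannon limit \eqn{\exp(-\sum_i p_i \ln p_i)} at q = 1.
#' q = 0 counts species, q = 1 weights species by their frequency
#' (exponential Shannon entropy, "common" species), q = 2 emphasises
#' dominants (inverse Simpson concentration). Zero entries contribute
#' nothing at any order.
#'
#' The q = 1 branch is taken analytically whenever `|q - 1| < 1e-9`, never by
#' numerical approach from nearby q, which avoids the floating-point blowup
#' of 1/(1-q).
#'
#' @param p numeric vector of proportions summing to 1 (tolerance 1e-9 by
#'   default; see `tol`). An unnormalised non-negative vector is accepted
#'   when `normalise = TRUE`.
#' @param q diversity order, a single non-negative number.
#' @param normalise divide `p` by its sum first (default FALSE: `p` must
#'   already be proportions).
#' @param tol tolerance on `sum(p) == 1`.
#' @return the effective number of species, a single number >= 1 for any
#'   non-empty community.
#' @examples
#' hill_number(c(0.5, 0.5), 0)        # 2 species
#' hill_number(c(0.8, 0.2), 1)        # about 1.649
#' hill_number(c(0.8, 0.2), 2)        # 1/0.68
#' @export
hill_number <- function(p, q, normalise = FALSE, tol = 1e-9) {
  stopifnot(length(q) == 1L, is.finite(q))
  if (q < 0) stop("diversity order q must be non-negative")
  if (anyNA(p) || any(p < 0)) stop("relative abundances must be non-negative")
  if (normalise) {
    s <- sum(p)
    if (s <= 0) stop("cannot normalise an all-zero abundance vector")
    p <- p / s
  } else if (abs(sum(p) - 1) > tol) {
    stop(sprintf("relative abundances must sum to 1 (got %.12g)", sum(p)))
  }
  p <- p[p > 0]
  if (!length(p)) return(0)
  if (abs(q - 1) < 1e-9) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

# rows of a (possibly classed) matrix as proportions, dropping empty species
.community_props <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) < 1) stop("need at least one community")
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop("empty community row(s): ", paste(rownames(m)[tot <= 0], collapse = ", "))
  }
  m / tot
}

#' Gamma diversity of N equally weighted communities
#'
#' Hill number of the equal-weight pooled proportions
#' \eqn{\bar p_i = N^{-1}\sum_j p_{ij}}, rows of `m` being communities.
#'
#' @param m communities-by-species matrix of counts, biomass, or proportions.
#' @param q diversity order.
#' @return effective number of species in the pooled assemblage.
#' @export
multi_gamma <- function(m, q) {
  p <- .community_props(m)
  hill_number(colMeans(p), q, tol = 1e-6)
}

#' Alpha diversity of N equally weighted communities
#'
#' The within-community component of the Hill-number partition with equal
#' community weights: for q != 1,
#' \deqn{{}^qD_\alpha = \left[\frac{1}{N}\sum_j\sum_i p_{ij}^q\right]^{1/(1-q)}}
#' and the exponential of the mean Shannon entropy at q = 1. Satisfies
#' gamma/alpha in \[1, N\].
#'
#' @inheritParams multi_gamma
#' @return equal-weight alpha diversity (effective species per community).
#' @export
multi_alpha <- function(m, q) {
  stopifnot(length(q) == 1L, is.finite(q))
  if (q < 0) stop("diversity order q must be non-negative")
  p <- .community_props(m)
  if (abs(q - 1) < 1e-9) {
    ent <- apply(p, 1, function(r) { r <- r[r > 0]; -sum(r * log(r)) })
    exp(mean(ent))
  } else {
    pq <- p^q
    pq[p == 0] <- 0  # zero entries contribute nothing even at q = 0
    mean(rowSums(pq))^(1 / (1 - q))
  }
}

#' Multi-assemblage overlap C_qN and its beta complement
#'
#' The overlap family transforms the beta component
#' \eqn{D_\beta = D_\gamma / D_\alpha} of N equally weighted communities onto
#' \[0, 1\], interpretable as the percentage species overlap:
#' \deqn{C_{qN} = \frac{(1/D_\beta)^{q-1} - (1/N)^{q-1}}{1 - (1/N)^{q-1}}, \quad q \ne 1}
#' with the Horn limit \eqn{C_{1N} = 1 - \ln D_\beta / \ln N} at q = 1.
#' q = 0 reduces to the multi-assemblage Sorensen index
#' \eqn{(N - S/\bar S)/(N - 1)}; q = 2 is the generalised multi-assemblage
#' Morisita-Horn index. Beta diversity on the same scale is simply
#' \eqn{{}^q\beta = 1 - C_{qN}}.
#'
#' @param m communities-by-species matrix (N >= 2 rows, each non-empty).
#' @param q diversity order (the pipeline uses 0, 1 and 2).
#' @param grain optional grain level recorded in the result.
#' @param habitat optional habitat label recorded in the result.
#' @return an object of class `overlap_result`: list with `q`, `N`, `CqN`,
#'   `beta` (= 1 - CqN), `gamma`, `alpha`, `D_beta`, `grain`, `habitat`,
#'   and `se` (NA until filled in by a bootstrap).
#' @examples
#' m <- rbind(a = c(1, 0), b = c(0.5, 0.5))
#' overlap_CqN(m, 2)$CqN  # 2/3, the pairwise Morisita-Horn
#' @export
overlap_CqN <- function(m, q, grain = NA_integer_, habitat = NA_character_) {
  m <- as.matrix(m)
  N <- nrow(m)
  if (N < 2) stop("overlap requires at least N = 2 communities")
  gamma <- multi_gamma(m, q)
  alpha <- multi_alpha(m, q)
  D_beta <- gamma / alpha
  if (D_beta < 1 - 1e-6 || D_beta > N + 1e-6) {
    stop(sprintf("internal consistency failure: D_beta = %.9g outside [1, N]", D_beta))
  }
  D_beta <- min(max(D_beta, 1), N)
  if (abs(q - 1) < 1e-9) {
    C <- 1 - log(D_beta) / log(N)
  } else {
    C <- ((1 / D_beta)^(q - 1) - (1 / N)^(q - 1)) / (1 - (1 / N)^(q - 1))
  }
  C <- min(max(C, 0), 1)
  structure(list(q = q, N = N, CqN = C, beta = 1 - C,
                 gamma = gamma, alpha = alpha, D_beta = D_beta,
                 se = NA_real_, grain = grain, habitat = habitat),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("C_qN overlap: q = %g, N = %d, C = %.4f, beta = %.4f%s\n",
              x$q, x$N, x$CqN, x$beta,
              if (is.finite(x$se)) sprintf(" (SE %.4f)", x$se) else ""))
  invisible(x)
}

#' Pairwise similarity between two communities
#'
#' [overlap_CqN()] with N = 2: the classic Sorensen (q = 0), Horn (q = 1)
#' and Morisita-Horn (q = 2) similarity indices.
#'
#' @param c1,c2 abundance (or proportion) vectors over the same species axis.
#' @param q diversity order.
#' @return similarity in \[0, 1\].
#' @examples
#' pairwise_similarity(c(1, 1, 0), c(0, 1, 1), 0)  # Sorensen = 0.5
#' @export
pairwise_similarity <- function(c1, c2, q) {
  if (length(c1) != length(c2)) stop("communities must share one species axis")
  if (sum(c1) <= 0 || sum(c2) <= 0) stop("both communities must be non-empty")
  overlap_CqN(rbind(c1, c2), q)$CqN
}

# all pairwise C_q2 values between the rows of X and the rows of Y,
# vectorised over the Y axis; same gamma/alpha math as overlap_CqN
.pairwise_CqN_matrix <- function(X, Y, q) {
  Px <- .community_props(X)
  Py <- .community_props(Y)
  nx <- nrow(Px); ny <- nrow(Py); S <- ncol(Px)
  pow_sum <- function(P) {
    Pq <- P^q
    Pq[P == 0] <- 0
    rowSums(Pq)
  }
  out <- matrix(NA_real_, nx, ny, dimnames = list(rownames(X), rownames(Y)))
  if (abs(q - 1) < 1e-9) {
    ent <- function(P) {
      Pl <- P * log(P)
      Pl[P == 0] <- 0
      -rowSums(Pl)
    }
    hx <- ent(Px); hy <- ent(Py)
    for (i in seq_len(nx)) {
      Pm <- (matrix(Px[i, ], ny, S, byrow = TRUE) + Py) / 2
      D_beta <- exp(ent(Pm) - (hx[i] + hy) / 2)
      out[i, ] <- 1 - log(pmin(pmax(D_beta, 1), 2)) / log(2)
    }
  } else {
    ax <- pow_sum(Px); ay <- pow_sum(Py)
    e <- 1 / (1 - q)
    for (i in seq_len(nx)) {
      Pm <- (matrix(Px[i, ], ny, S, byrow = TRUE) + Py) / 2
      gamma <- pow_sum(Pm)^e
      alpha <- ((ax[i] + ay) / 2)^e
      D_beta <- pmin(pmax(gamma / alpha, 1), 2)
      out[i, ] <- ((1 / D_beta)^(q - 1) - 0.5^(q - 1)) / (1 - 0.5^(q - 1))
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Mean between-habitat pairwise similarity at a grain
#'
#' Averages [pairwise_similarity()] over every oil-palm x forest pair of
#' communities at one grain. The standard error is obtained by bootstrap
#' (default 500 iterations) over the pair members: the communities of each
#' habitat are resampled and the mean recomputed.
#'
#' @param matrix abundance matrix at the grain (rows = grain units).
#' @param metadata data frame with `sample_id` and `habitat` covering the
#'   rows of `matrix`.
#' @param q diversity order.
#' @param B bootstrap iterations for the SE (default 500); `B = 0` skips it.
#' @param seed optional integer seed for the bootstrap.
#' @param scheme bootstrap resampling scheme, see [bootstrap_statistic()].
#' @return list with `mean`, `se`, `n_pairs`, `q`, and the matrix of
#'   pairwise similarities (`values`, oil palm rows x forest columns).
#' @export
mean_pairwise_between <- function(matrix, metadata, q, B = 500, seed = NULL,
                                  scheme = c("resample_units", "resample_individuals")) {
  scheme <- match.arg(scheme)
  hab <- metadata$habitat[match(rownames(matrix), metadata$sample_id)]
  if (anyNA(hab)) stop("metadata does not cover all matrix samples")
  rows_op <- which(hab == "oil_palm")
  rows_fo <- which(hab == "forest")
  if (!length(rows_op) || !length(rows_fo)) {
    stop("both habitats must be present at this grain")
  }
  pair_mean <- function(m, i_op, i_fo) {
    .pairwise_CqN_matrix(m[i_op, , drop = FALSE], m[i_fo, , drop = FALSE], q)
  }
  vals <- pair_mean(unclass(matrix), rows_op, rows_fo)
  se <- NA_real_
  if (B > 0) {
    boot <- bootstrap_statistic(
      matrix, B = B, seed = seed, scheme = scheme,
      groups = hab,
      statistic = function(m, idx) {
        g <- hab[idx]
        mean(pair_mean(unclass(m), which(g == "oil_palm"), which(g == "forest")))
      })
    se <- boot$se
  }
  list(mean = mean(vals), se = se, n_pairs = length(vals), q = q, values = vals)
}

#' Remove singleton species from a count matrix
#'
#' A singleton is a species whose total count across the analysis set equals
#' exactly one individual. Defined on counts only: biomass carries no notion
#' of an individual, so singleton filtering must happen before biomass
#' conversion.
#'
#' @param matrix a count [abundance_matrix()].
#' @param species optional vector mapping columns to species ids (for
#'   caste-split columns); totals are formed per species.
#' @return the matrix without singleton species; idempotent.
#' @export
remove_singletons <- function(matrix, species = colnames(matrix)) {
  if (value_kind(matrix) != "count") {
    stop("singletons are defined on counts; filter before biomass conversion")
  }
  tot <- tapply(colSums(matrix), species, sum)
  singleton_sp <- names(tot)[tot == 1]
  matrix[, !(species %in% singleton_sp), drop = FALSE]
}

#' Top-ranked species by mean biomass per grain unit
#'
#' Per-species mean biomass per unit of occurrence (grain), sorted
#' descending; the analogue of a rank-abundance table with biomass as the
#' abundance currency. Ties are broken by species id.
#'
#' @param matrix a biomass [abundance_matrix()] at one grain.
#' @param k number of species to keep (default 20); capped at the species
#'   count.
#' @return data frame with `rank`, `species_id`, `mean_biomass_mg`.
#' @export
top_biomass_ranks <- function(matrix, k = 20) {
  mean_per_unit <- colSums(matrix) / nrow(matrix)
  ord <- order(-mean_per_unit, colnames(matrix))
  k <- min(k, ncol(matrix))
  sel <- ord[seq_len(k)]
  data.frame(rank = seq_len(k),
             species_id = colnames(matrix)[sel],
             mean_biomass_mg = unname(mean_per_unit[sel]),
             stringsAsFactors = FALSE)
}

#' Mean per-sample Hill diversity at a grain, with bootstrap SE
#'
#' Arithmetic mean over samples of the per-sample Hill number (each sample
#' treated as one community). At q = 0 this is mean observed richness; q = 1
#' the mean effective number of common species; q = 2 of dominant species.
#'
#' @param matrix abundance matrix at one grain (rows = grain units).
#' @param q diversity order.
#' @param B bootstrap iterations for the SE (over samples, with
#'   replacement); `B = 0` skips the SE.
#' @param seed optional integer seed.
#' @return list with `mean`, `se`, `q`, `n`, and the per-sample `values`.
#' @export
mean_alpha <- function(matrix, q, B = 1000, seed = NULL) {
  if (nrow(matrix) < 1) stop("need at least one sample")
  vals <- apply(unclass(matrix), 1, hill_number, q = q, normalise = TRUE)
  se <- NA_real_
  if (B > 0) {
    boot <- bootstrap_statistic(matrix, B = B, seed = seed,
                                scheme = "resample_units",
                                statistic = function(m, idx) {
                                  mean(apply(unclass(m), 1, hill_number,
                                             q = q, normalise = TRUE))
                                })
    se <- boot$se
  }
  list(mean = mean(vals), se = se, q = q, n = nrow(matrix), values = vals)
}
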