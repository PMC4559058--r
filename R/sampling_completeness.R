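#' Sample-based rarefied species richness
#'
#' Expected number of species in `m` samples drawn without replacement from
#' the `T` available, by the analytic hypergeometric interpolation
#' \deqn{S(m) = \sum_i \left[1 - \binom{T - T_i}{m} \Big/ \binom{T}{m}\right]}
#' where \eqn{T_i} is the number of samples in which species i occurs
#' (undefined binomial coefficients count as 0). Interpolation only — no
#' extrapolation beyond the observed number of samples.
#'
#' @param matrix abundance (or incidence) matrix, rows = samples; only
#'   presence/absence is used.
#' @param m number of samples, one or more values in `1..nrow(matrix)`.
#' @return numeric vector of expected richness, one per `m`.
#' @export
rarefy_richness <- function(matrix, m) {
  Tn <- nrow(matrix)
  if (any(m < 1 | m > Tn)) stop("m must lie in 1..", Tn)
  Ti <- colSums(unclass(matrix) > 0)
  Ti <- Ti[Ti > 0]
  vapply(m, function(mm) {
    # lchoose is NA-free: choose(n, k) = 0 when n < k
    frac <- exp(lchoose(Tn - Ti, mm) - lchoose(Tn, mm))
    frac[Tn - Ti < mm] <- 0
    sum(1 - frac)
  }, numeric(1))
}

#' Full sample-based rarefaction curve
#'
#' @param matrix abundance matrix (rows = samples).
#' @param habitat optional label stored on the result.
#' @return data frame with `m` (1..T), `expected_richness`, `habitat`.
#' @export
rarefaction_curve <- function(matrix, habitat = NA_character_) {
  m <- seq_len(nrow(matrix))
  data.frame(m = m, expected_richness = rarefy_richness(matrix, m),
             habitat = habitat, stringsAsFactors = FALSE)
}

#' Sample coverage of a count vector
#'
#' The estimated proportion of total community abundance belonging to
#' species represented in the sample:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}}
#' with \eqn{f_1} singletons, \eqn{f_2} doubletons, and \eqn{\hat C = 1}
#' when there are no singletons.
#'
#' @param counts integer count vector (one pooled assemblage).
#' @return list with `n`, `f1`, `f2`, `coverage`.
#' @examples
#' coverage(c(2, 1, 1))$coverage  # 0.625
#' @export
coverage <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (length(counts) == 0 || n < 1) stop("coverage needs a non-empty sample")
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  C <- if (f1 == 0) 1 else 1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  list(n = n, f1 = f1, f2 = f2, coverage = max(0, min(1, C)))
}

#' Coverage as a function of the number of pooled samples
#'
#' For each subset size `m = 1..T`, the mean coverage of `m` pooled samples.
#' All subsets are enumerated when there are at most `max_exact` of them,
#' otherwise `R` random subsets are averaged (seeded).
#'
#' @param matrix count matrix (rows = samples).
#' @param habitat optional label stored on the result.
#' @param R number of random subsets per `m` when enumeration is infeasible.
#' @param max_exact largest subset count for exhaustive enumeration.
#' @param seed optional integer seed for the random subsets.
#' @return data frame with `m`, `coverage`, `exact` (logical), `habitat`.
#' @export
coverage_curve <- function(matrix, habitat = NA_character_, R = 200,
                           max_exact = 200, seed = NULL) {
  Tn <- nrow(matrix)
  m0 <- unclass(matrix)
  one <- function(mm) {
    n_subsets <- choose(Tn, mm)
    if (n_subsets <= max_exact) {
      subs <- utils::combn(Tn, mm, simplify = FALSE)
      vals <- vapply(subs, function(ix) {
        coverage(colSums(m0[ix, , drop = FALSE]))$coverage
      }, numeric(1))
      c(mean(vals), 1)
    } else {
      vals <- vapply(seq_len(R), function(r) {
        ix <- sample.int(Tn, mm)
        coverage(colSums(m0[ix, , drop = FALSE]))$coverage
      }, numeric(1))
      c(mean(vals), 0)
    }
  }
  run <- function() t(vapply(seq_len(Tn), one, numeric(2)))
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  data.frame(m = seq_len(Tn), coverage = res[, 1], exact = res[, 2] == 1,
             habitat = habitat, stringsAsFactors = FALSE)
}
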