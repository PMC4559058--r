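#' Bootstrap a community statistic
#'
#' Two resampling schemes are supported. `resample_units` draws communities
#' (matrix rows) with replacement — stratified within `groups` when given, so
#' that e.g. both habitats stay represented. `resample_individuals` keeps the
#' communities fixed and redraws each one's individuals from a multinomial at
#' its observed depth; it requires integral counts and is the natural scheme
#' when the units of a grain are single plots and unit resampling would be
#' degenerate.
#'
#' A statistic that fails on a resample (e.g. a degenerate community) is
#' recorded and the resample redrawn; the count of redraws is reported.
#'
#' @param matrix abundance matrix (rows = communities).
#' @param statistic function of `(m, idx)` where `m` is the resampled matrix
#'   and `idx` the row indices drawn (equal to `seq_len(nrow)` under
#'   `resample_individuals`); must return a single number.
#' @param B number of bootstrap iterations (>= 2).
#' @param seed optional integer seed (local RNG; the caller's RNG state is
#'   untouched).
#' @param scheme `"resample_units"` or `"resample_individuals"`.
#' @param groups optional vector (length `nrow(matrix)`) of strata for
#'   `resample_units`.
#' @param max_redraw cap on failed-resample redraws before erroring.
#' @return object of class `bootstrap_result`: list with `estimate` (the
#'   statistic on the original data), `se` (SD over resamples), `B`,
#'   `scheme`, `seed`, `n_failed`, and the resample `values`.
#' @export
bootstrap_statistic <- function(matrix, statistic, B = 1000, seed = NULL,
                                scheme = c("resample_units", "resample_individuals"),
                                groups = NULL, max_redraw = 100) {
  scheme <- match.arg(scheme)
  if (B < 2) stop("bootstrap needs B >= 2 iterations")
  m0 <- unclass(as.matrix(matrix))
  n <- nrow(m0)
  if (scheme == "resample_individuals") {
    tot <- rowSums(m0)
    if (any(abs(m0 - round(m0)) > 1e-8)) {
      stop("resample_individuals requires integral counts")
    }
  }
  est <- statistic(matrix, seq_len(n))
  run <- function() {
    vals <- numeric(B)
    n_failed <- 0L
    for (b in seq_len(B)) {
      ok <- FALSE
      tries <- 0L
      while (!ok) {
        if (scheme == "resample_units") {
          if (is.null(groups)) {
            idx <- sample.int(n, n, replace = TRUE)
          } else {
            idx <- unlist(lapply(split(seq_len(n), groups), function(i) {
              i[sample.int(length(i), length(i), replace = TRUE)]
            }), use.names = FALSE)
          }
          mb <- m0[idx, , drop = FALSE]
        } else {
          idx <- seq_len(n)
          mb <- t(vapply(seq_len(n), function(i) {
            as.numeric(stats::rmultinom(1, size = round(tot[i]),
                                        prob = m0[i, ] / tot[i]))
          }, numeric(ncol(m0))))
          dimnames(mb) <- dimnames(m0)
        }
        v <- tryCatch(statistic(mb, idx), error = function(e) NA_real_)
        if (is.finite(v)) {
          vals[b] <- v
          ok <- TRUE
        } else {
          n_failed <- n_failed + 1L
          tries <- tries + 1L
          if (tries > max_redraw) stop("statistic failed on ", max_redraw,
                                       " consecutive resamples")
        }
      }
    }
    list(vals = vals, n_failed = n_failed)
  }
  r <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(estimate = est, se = stats::sd(r$vals), B = B,
                 scheme = scheme, seed = seed, n_failed = r$n_failed,
                 values = r$vals),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (%s, B = %d): estimate = %.5g, SE = %.5g\n",
              x$scheme, x$B, x$estimate, x$se))
  invisible(x)
}

#' Standardized Z test between two bootstrap estimates
#'
#' \eqn{z = (est_1 - est_2)/\sqrt{SE_1^2 + SE_2^2}} with a two-sided p-value
#' from the standard normal.
#'
#' @param est1,se1 first estimate and its standard error.
#' @param est2,se2 second estimate and its standard error.
#' @param labels character vector of length 2 naming the two quantities.
#' @return data frame row with `label1`, `label2`, `difference`, `z`, `p`.
#' @examples
#' z_test(1.0, 0.1, 0.8, 0.1)  # z = 1.414, p about 0.157
#' @export
z_test <- function(est1, se1, est2, se2, labels = c("a", "b")) {
  if (se1^2 + se2^2 <= 0) stop("both standard errors are zero; Z undefined")
  z <- (est1 - est2) / sqrt(se1^2 + se2^2)
  data.frame(label1 = labels[1], label2 = labels[2],
             difference = est1 - est2, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR control over a family of tests
#'
#' Step-up procedure at level `alpha`: p-values are compared in ascending
#' order against `k * alpha / m` and everything up to the largest passing
#' rank is rejected. Adjusted p-values come from [stats::p.adjust()]
#' (method `"BH"`).
#'
#' @param p vector of p-values in \[0, 1\].
#' @param alpha target false discovery rate (default 0.05).
#' @return data frame with `p`, `p_adjusted`, `reject` in the input order.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Compare a set of labelled estimates with Z tests plus FDR correction
#'
#' Runs [z_test()] on each requested pair and corrects the resulting family
#' of p-values with [bh_fdr()]. The family should correspond to one
#' comparison set (e.g. the three between-grain contrasts for a fixed q and
#' habitat).
#'
#' @param estimates data frame with columns `label`, `estimate`, `se`.
#' @param pairs two-column matrix (or data frame) of label pairs to test;
#'   default: all unordered pairs.
#' @param alpha FDR level.
#' @return data frame of comparisons with `difference`, `z`, `p`,
#'   `p_adjusted`, `reject`.
#' @export
compare_estimates <- function(estimates, pairs = NULL, alpha = 0.05) {
  stopifnot(all(c("label", "estimate", "se") %in% names(estimates)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(estimates$label, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- match(pairs[i, 1], estimates$label)
    b <- match(pairs[i, 2], estimates$label)
    if (is.na(a) || is.na(b)) stop("unknown label in comparison pairs")
    z_test_safe(estimates$estimate[a], estimates$se[a],
                estimates$estimate[b], estimates$se[b],
                labels = c(estimates$label[a], estimates$label[b]))
  })
  out <- do.call(rbind, rows)
  fdr_augment(out, alpha)
}

# z_test that records a degenerate comparison (both SEs zero) as NA
# rather than aborting a whole report
z_test_safe <- function(est1, se1, est2, se2, labels = c("a", "b")) {
  if (se1^2 + se2^2 <= 0) {
    return(data.frame(label1 = labels[1], label2 = labels[2],
                      difference = est1 - est2, z = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  z_test(est1, se1, est2, se2, labels)
}

# attach BH-adjusted p-values and decisions, tolerating NA comparisons
fdr_augment <- function(out, alpha) {
  ok <- !is.na(out$p)
  out$p_adjusted <- NA_real_
  out$reject <- NA
  if (any(ok)) {
    fdr <- bh_fdr(out$p[ok], alpha)
    out$p_adjusted[ok] <- fdr$p_adjusted
    out$reject[ok] <- fdr$reject
  }
  out
}
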