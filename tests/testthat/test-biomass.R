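make_traits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(species_id = r$id, subfamily = r$sf,
               caste = if (is.null(r$caste)) "none" else r$caste,
               dimension_type = dimension_for_subfamily(r$sf),
               dimension_mm = r$dim,
               dry_weights_mg = I(list(if (is.null(r$w)) numeric(0) else r$w)),
               stringsAsFactors = FALSE)
  }))
  validate_traits(df)
}

test_that("measured mean weights require at least three specimens", {
  tr <- make_traits(list(id = "spA", sf = "Myrmicinae", dim = 1, w = c(1, 2, 3)),
                    list(id = "spB", sf = "Myrmicinae", dim = 1, w = c(1, 2)),
                    list(id = "spC", sf = "Myrmicinae", dim = 1, w = c(7, 7, 7, 7)))
  m <- mean_measured_weight(tr, "spA")
  expect_equal(m$mean_weight_mg, 2)
  expect_equal(m$source, "measured")
  expect_null(mean_measured_weight(tr, "spB"))
  expect_equal(mean_measured_weight(tr, "spC")$mean_weight_mg, 7)
})

test_that("allometry recovers a noiseless power law exactly", {
  L <- c(0.5, 0.8, 1.2, 2.0)
  tr <- do.call(make_traits, lapply(seq_along(L), function(i) {
    w <- 2 * L[i]^3
    list(id = paste0("sp", i), sf = "Ponerinae", dim = L[i], w = rep(w, 3))
  }))
  models <- fit_allometry(tr)
  expect_equal(models$tibia_length$slope, 3, tolerance = 1e-9)
  expect_equal(models$tibia_length$intercept, log(2), tolerance = 1e-9)
  expect_equal(predict_weight(models$tibia_length, 1.5), 2 * 1.5^3,
               tolerance = 1e-9)
  # predictions are positive for any positive dimension
  expect_true(all(predict_weight(models$pooled, c(1e-3, 0.1, 10)) > 0))
  expect_error(predict_weight(models$pooled, -1), "positive")
})

test_that("allometry matches the normal-equation least-squares oracle", {
  withr::with_seed(8, {
    L <- runif(8, 0.4, 3)
    W <- 0.6 * L^2.4 * exp(rnorm(8, 0, 0.2))
    tr <- do.call(make_traits, lapply(1:8, function(i) {
      list(id = paste0("sp", i), sf = "Formicinae", dim = L[i], w = rep(W[i], 3))
    }))
    models <- fit_allometry(tr)
    X <- cbind(1, log(L))
    beta <- solve(t(X) %*% X, t(X) %*% log(W))
    expect_equal(models$head_length$intercept, beta[1], tolerance = 1e-9)
    expect_equal(models$head_length$slope, beta[2], tolerance = 1e-9)
    # duplicating a point off the line changes the fit; on the line it cannot
    on_line <- exp(beta[1]) * 1.1^beta[2]
    tr2 <- do.call(make_traits, c(lapply(1:8, function(i) {
      list(id = paste0("sp", i), sf = "Formicinae", dim = L[i], w = rep(W[i], 3))
    }), list(list(id = "sp9", sf = "Formicinae", dim = 1.1, w = rep(on_line, 3)))))
    m2 <- fit_allometry(tr2)
    expect_equal(m2$head_length$slope, beta[2], tolerance = 1e-9)
  })
})

test_that("degenerate allometry inputs error with the group named", {
  tr <- make_traits(list(id = "spA", sf = "Ponerinae", dim = 1, w = c(1, 1, 1)))
  expect_error(fit_allometry(tr), "tibia_length")
})

test_that("subfamily routing maps the five printed groups and pools the rest", {
  expect_equal(dimension_for_subfamily(c("Dolichoderinae", "Formicinae",
                                         "Pseudomyrmecinae")),
               rep("head_length", 3))
  expect_equal(dimension_for_subfamily("Ponerinae"), "tibia_length")
  expect_equal(dimension_for_subfamily("Myrmicinae"), "pronotum_width")
  expect_equal(dimension_for_subfamily(c("Dorylinae", "Leptanillinae")),
               rep("pooled", 2))
})

test_that("counts_to_biomass multiplies, collapses castes and conserves totals", {
  w <- data.frame(species_id = c("spA", "spA", "spB"),
                  caste = c("major", "minor", "none"),
                  mean_weight_mg = c(1.0, 0.2, 0.5),
                  source = "measured", stringsAsFactors = FALSE)
  cts <- abundance_matrix(rbind(s1 = c(spA_major = 2, spA_minor = 10, spB = 3),
                                s2 = c(spA_major = 0, spA_minor = 5, spB = 0)))
  bm <- counts_to_biomass(cts, w)
  expect_equal(value_kind(bm), "biomass")
  expect_equal(colnames(bm), c("spA", "spB"))
  expect_equal(bm["s1", "spA"], 2 * 1.0 + 10 * 0.2)  # majors + minors = 4 mg
  expect_equal(bm["s1", "spB"], 1.5)                 # 3 x 0.5 mg
  expect_equal(sum(bm), sum(unclass(cts) %*% c(1.0, 0.2, 0.5)))
  # linearity: scaling counts by k scales biomass by k
  bm3 <- counts_to_biomass(abundance_matrix(unclass(cts) * 3), w)
  expect_equal(unclass(bm3), unclass(bm) * 3, tolerance = 1e-12)
  # unity weights: biomass equals collapsed counts
  w1 <- transform(w, mean_weight_mg = 1)
  expect_equal(unclass(counts_to_biomass(cts, w1)),
               unclass(collapse_castes(cts)), ignore_attr = TRUE)
})

test_that("species lacking both weights and dimensions are reported together", {
  tr <- make_traits(list(id = "spA", sf = "Myrmicinae", dim = 0.9, w = c(1, 2, 3)),
                    list(id = "spB", sf = "Myrmicinae", dim = 1.4, w = c(2, 2, 4)))
  tr2 <- rbind(tr, data.frame(species_id = "spC", subfamily = "Myrmicinae",
                              caste = "none", dimension_type = "pronotum_width",
                              dimension_mm = NA_real_,
                              dry_weights_mg = I(list(numeric(0)))))
  expect_error(species_weights(tr2), "spC")
  # with a dimension, spC gets a positive predicted weight
  tr2$dimension_mm[3] <- 1.1
  w <- species_weights(tr2)
  expect_equal(w$source, c("measured", "measured", "predicted"))
  expect_true(all(w$mean_weight_mg > 0))
})
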