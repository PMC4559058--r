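# metadata for plots on an east-west line at the equator, positions in km
line_metadata <- function(ids, km, habitat = "oil_palm") {
  toy_metadata(ids, habitat, lat = rep(0, length(ids)),
               lon = km / (pi * 6371 / 180))
}

test_that("haversine distances: zero diagonal, symmetry, 1 degree latitude", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   latitude = c(5, 6, 5), longitude = c(117, 117, 117))
  d <- pairwise_distance(md)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "b"], pi * 6371 / 180, tolerance = 1e-4)  # ~111.19 km
  expect_equal(d["a", "c"], 0)
  md$latitude[1] <- NA
  expect_error(pairwise_distance(md), "missing coordinates")
})

test_that("greedy pairing matches the exhaustive-matching oracle on a line", {
  md <- line_metadata(c("p1", "p2", "p3", "p4"), c(0, 1, 10, 11))
  d <- pairwise_distance(md)
  res <- pair_samples(md, d, max_km = 5)
  expect_equal(nrow(res$pairs), 2)
  expect_setequal(res$pairs$unit_id, c("p1+p2", "p3+p4"))
  expect_length(res$omitted, 0)
  # oracle: among all ways to partition 4 plots into 2 pairs, only
  # {p1,p2},{p3,p4} respects the 5 km cap
  matchings <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                    list(c(1, 4), c(2, 3)))
  feasible <- Filter(function(mt) all(vapply(mt, function(pr) {
    d[pr[1], pr[2]] <= 5
  }, logical(1))), matchings)
  expect_length(feasible, 1)
  expect_equal(feasible[[1]], list(c(1, 2), c(3, 4)))
})

test_that("odd and isolated plots are omitted, never silently dropped", {
  md3 <- line_metadata(c("p1", "p2", "p3"), c(0, 1, 2))
  res3 <- pair_samples(md3, pairwise_distance(md3), max_km = 5)
  expect_equal(nrow(res3$pairs), 1)
  expect_length(res3$omitted, 1)

  md_far <- line_metadata(c("p1", "p2", "p3"), c(0, 20, 40))
  res_far <- pair_samples(md_far, pairwise_distance(md_far), max_km = 5)
  expect_equal(nrow(res_far$pairs), 0)
  expect_setequal(res_far$omitted, c("p1", "p2", "p3"))
})

test_that("pooling sums constituent rows and conserves the grand total", {
  m <- abundance_matrix(rbind(p1 = c(a = 3, b = 0), p2 = c(a = 1, b = 2),
                              p3 = c(a = 0, b = 5), p4 = c(a = 2, b = 2)))
  pairing <- data.frame(unit_id = c("u1", "u2"),
                        member1 = c("p1", "p3"), member2 = c("p2", "p4"))
  pooled <- pool_samples(m, pairing)
  expect_equal(unclass(pooled),
               rbind(u1 = c(a = 4, b = 2), u2 = c(a = 2, b = 7)),
               ignore_attr = TRUE)
  expect_equal(sum(pooled), sum(m))
  expect_equal(value_kind(pooled), "count")
  # identity pairing leaves the matrix unchanged
  idp <- data.frame(unit_id = rownames(m), members = I(as.list(rownames(m))))
  expect_equal(unclass(pool_samples(m, idp)), unclass(m))
  # a sample in two units is an error
  bad <- data.frame(unit_id = c("u1", "u2"),
                    member1 = c("p1", "p1"), member2 = c("p2", "p3"))
  expect_error(pool_samples(m, bad), "more than one unit")
})

test_that("the synthetic layout reproduces the printed unit counts per level", {
  land <- generate_landscape(synthetic_truth(seed = 2, individuals_per_plot = 60))
  h <- build_hierarchy(land$counts, land$metadata)
  hab_of <- function(lv) {
    md <- h[[lv]]$metadata
    table(md$habitat)
  }
  expect_equal(as.numeric(hab_of("grain1")[c("oil_palm", "forest")]), c(26, 21))
  expect_equal(as.numeric(hab_of("grain2")[c("oil_palm", "forest")]), c(13, 10))
  expect_equal(as.numeric(hab_of("grain3")[c("oil_palm", "forest")]), c(6, 5))
  expect_length(h$grain2$omitted, 1)   # the unpairable forest plot
  expect_length(h$grain3$omitted, 1)   # the leftover oil palm pair
})

test_that("the hierarchy is strictly nested and conserves abundance", {
  land <- generate_landscape(synthetic_truth(seed = 5, individuals_per_plot = 60))
  h <- build_hierarchy(land$counts, land$metadata)
  # every grain-3 unit is the union of exactly two grain-2 units (4 plots)
  for (u in names(h$grain3$units)) {
    members <- h$grain3$units[[u]]
    expect_length(members, 4)
    g2_units <- Filter(function(g2) all(h$grain2$units[[g2]] %in% members),
                       names(h$grain2$units))
    expect_length(g2_units, 2)
  }
  for (u in names(h$grain2$units)) expect_length(h$grain2$units[[u]], 2)
  # abundance conservation: pooled column sums equal sums over retained plots
  for (lv in c("grain2", "grain3")) {
    retained <- unlist(h[[lv]]$units)
    expect_equal(colSums(h[[lv]]$matrix),
                 colSums(h$grain1$matrix[retained, , drop = FALSE]))
  }
  # deterministic given inputs
  h2 <- build_hierarchy(land$counts, land$metadata)
  expect_identical(h2$grain3$units, h$grain3$units)
})

test_that("four plots in one tight cluster pool to two pairs and one grain-3 unit", {
  md <- line_metadata(c("p1", "p2", "p3", "p4"), c(0, 1, 8, 9))
  m <- abundance_matrix(matrix(1, 4, 3,
                               dimnames = list(md$sample_id, c("a", "b", "c"))))
  h <- suppressWarnings(build_hierarchy(m, md))
  expect_equal(nrow(h$grain2$matrix), 2)
  expect_equal(nrow(h$grain3$matrix), 1)
  expect_equal(sort(h$grain3$units[[1]]), c("p1", "p2", "p3", "p4"))
})

test_that("an explicit pairing override replaces greedy matching", {
  md <- line_metadata(c("p1", "p2", "p3", "p4"), c(0, 1, 2, 3))
  m <- abundance_matrix(matrix(1:12, 4, 3,
                               dimnames = list(md$sample_id, c("a", "b", "c"))))
  ov <- data.frame(unit_id = c("u1", "u2"),
                   member1 = c("p1", "p2"), member2 = c("p4", "p3"))
  h <- suppressWarnings(build_hierarchy(m, md, pairing_override = list(grain2 = ov)))
  expect_setequal(names(h$grain2$units), c("u1", "u2"))
  expect_equal(sort(h$grain2$units$u1), c("p1", "p4"))
})
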