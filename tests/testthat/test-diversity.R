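test_that("hill_number matches its closed forms", {
  for (q in c(0, 0.5, 1, 2, 5)) {
    expect_equal(hill_number(c(0.5, 0.5), q), 2)
  }
  expect_equal(hill_number(c(0.8, 0.2), 1),
               exp(-(0.8 * log(0.8) + 0.2 * log(0.2))), tolerance = 1e-12)
  expect_equal(hill_number(c(0.8, 0.2), 2), 1 / 0.68, tolerance = 1e-12)
  expect_equal(hill_number(c(0.3, 0.7, 0), 0), 2)  # zeros contribute nothing
  expect_error(hill_number(c(0.5, 0.4), 2), "sum to 1")
  expect_error(hill_number(c(-0.2, 1.2), 2), "non-negative")
})

test_that("hill_number agrees with the Renyi-entropy oracle and is non-increasing in q", {
  skip_if_not_installed("vegan")
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- rgamma(12, 0.4)
      p <- p / sum(p)
      qs <- c(0, 0.5, 1, 2, 4)
      d <- vapply(qs, function(q) hill_number(p, q), numeric(1))
      expect_true(all(diff(d) <= 1e-10))
      ref <- exp(as.numeric(vegan::renyi(p, scales = qs)))
      expect_equal(d, ref, tolerance = 1e-8)
    }
  })
})

test_that("multi-assemblage gamma and alpha match hand computations", {
  m <- rbind(a = c(1, 0), b = c(0.5, 0.5))
  expect_equal(multi_gamma(m, 2), 1.6, tolerance = 1e-12)
  expect_equal(multi_alpha(m, 2), 4 / 3, tolerance = 1e-12)
  # identical communities: both equal the single-community diversity
  p <- c(0.6, 0.3, 0.1)
  mm <- rbind(p, p, p)
  for (q in c(0, 1, 2)) {
    expect_equal(multi_gamma(mm, q), hill_number(p, q), tolerance = 1e-12)
    expect_equal(multi_alpha(mm, q), hill_number(p, q), tolerance = 1e-12)
  }
  # disjoint single-species communities
  dd <- rbind(c(1, 0), c(0, 1))
  expect_equal(multi_gamma(dd, 0), 2)
  expect_equal(multi_alpha(dd, 0), 1)
})

test_that("overlap_CqN reduces to the classic pairwise indices at N = 2", {
  m <- rbind(a = c(1, 0), b = c(0.5, 0.5))
  expect_equal(overlap_CqN(m, 2)$CqN, 2 / 3, tolerance = 1e-12)
  expect_equal(overlap_CqN(m, 2)$CqN,
               oracle_morisita_horn(c(1, 0), c(0.5, 0.5)), tolerance = 1e-12)
  withr::with_seed(9, {
    for (i in 1:50) {
      cm <- random_pair(S = 25, shared_frac = runif(1, 0.2, 0.9))
      for (q in c(0, 1, 2)) {
        expect_equal(pairwise_similarity(cm$x, cm$y, q),
                     oracle_pairwise(cm$x, cm$y, q), tolerance = 1e-9)
      }
    }
  })
})

test_that("overlap_CqN behaves at its boundary cases", {
  p <- c(3, 2, 1, 4)
  m_id <- rbind(p, p, p)
  for (q in c(0, 1, 2)) {
    r <- overlap_CqN(m_id, q)
    expect_equal(r$CqN, 1, tolerance = 1e-9)
    expect_equal(r$beta, 0, tolerance = 1e-9)
  }
  dis <- rbind(c(1, 1, 0, 0), c(0, 0, 2, 3))
  expect_equal(overlap_CqN(dis, 0)$CqN, 0, tolerance = 1e-12)
  expect_error(overlap_CqN(rbind(c(1, 2)), 0), "N = 2")
})

test_that("CqN invariants hold on random multi-assemblage matrices", {
  withr::with_seed(21, {
    for (i in 1:25) {
      N <- sample(2:6, 1)
      m <- matrix(rgamma(N * 15, 0.4), N, 15)
      m[sample(length(m), round(length(m) * 0.3))] <- 0
      m <- m[rowSums(m) > 0, , drop = FALSE]
      if (nrow(m) < 2) next
      N <- nrow(m)
      for (q in c(0, 0.5, 1, 2, 3)) {
        r <- overlap_CqN(m, q)
        expect_gte(r$D_beta, 1)
        expect_lte(r$D_beta, N)
        expect_gte(r$CqN, 0)
        expect_lte(r$CqN, 1)
        expect_identical(r$beta, 1 - r$CqN)
        # permutation invariance
        perm <- sample.int(N)
        r2 <- overlap_CqN(m[perm, , drop = FALSE], q)
        expect_equal(r2$CqN, r$CqN, tolerance = 1e-12)
      }
      # continuity of the q -> 1 limit
      c_lim <- overlap_CqN(m, 1)$CqN
      expect_lt(abs(overlap_CqN(m, 1 + 1e-6)$CqN - c_lim), 1e-4)
      expect_lt(abs(overlap_CqN(m, 1 - 1e-6)$CqN - c_lim), 1e-4)
    }
  })
})

test_that("C_0N for equal communities sharing a fraction of species matches the closed form", {
  # N communities, each with S equally abundant species, all sharing the
  # same core of f*S species; the rest disjoint.
  withr::with_seed(31, {
    for (i in 1:10) {
      N <- sample(2:4, 1); S <- 12; n_shared <- sample(c(0, 3, 6, 12), 1)
      n_own <- S - n_shared
      total_sp <- n_shared + N * n_own
      m <- matrix(0, N, total_sp)
      if (n_shared > 0) m[, seq_len(n_shared)] <- 1
      for (j in seq_len(N)) {
        if (n_own > 0) {
          cols <- n_shared + (j - 1) * n_own + seq_len(n_own)
          m[j, cols] <- 1
        }
      }
      S_tot <- n_shared + N * n_own
      S_bar <- S
      expected <- (N - S_tot / S_bar) / (N - 1)
      expect_equal(overlap_CqN(m, 0)$CqN, expected, tolerance = 1e-12)
    }
  })
})

test_that("mean pairwise between-habitat similarity equals brute-force enumeration", {
  m <- abundance_matrix(rbind(o1 = c(a = 4, b = 1, c = 0),
                              o2 = c(a = 1, b = 3, c = 1),
                              f1 = c(a = 0, b = 2, c = 5),
                              f2 = c(a = 2, b = 0, c = 2)))
  md <- toy_metadata(rownames(m), c("oil_palm", "oil_palm", "forest", "forest"))
  for (q in c(0, 1, 2)) {
    res <- mean_pairwise_between(m, md, q, B = 0)
    brute <- mean(c(pairwise_similarity(m["o1", ], m["f1", ], q),
                    pairwise_similarity(m["o1", ], m["f2", ], q),
                    pairwise_similarity(m["o2", ], m["f1", ], q),
                    pairwise_similarity(m["o2", ], m["f2", ], q)))
    expect_equal(res$mean, brute, tolerance = 1e-12)
    expect_equal(res$n_pairs, 4L)
  }
  # one community per habitat: mean is the single pairwise value
  res1 <- mean_pairwise_between(m[c(1, 3), ], md, 2, B = 0)
  expect_equal(res1$mean, pairwise_similarity(m["o1", ], m["f1", ], 2))
  # identical communities: mean 1, bootstrap SE 0
  mi <- abundance_matrix(rbind(o1 = c(a = 2, b = 2), f1 = c(a = 2, b = 2)))
  res_id <- mean_pairwise_between(mi, toy_metadata(c("o1", "f1"),
                                                   c("oil_palm", "forest")),
                                  1, B = 50, seed = 5)
  expect_equal(res_id$mean, 1, tolerance = 1e-9)
  expect_equal(res_id$se, 0, tolerance = 1e-12)
})

test_that("singleton removal uses total counts and refuses biomass", {
  m <- abundance_matrix(rbind(s1 = c(a = 1, b = 1, c = 3),
                              s2 = c(a = 0, b = 1, c = 2)))
  out <- remove_singletons(m)
  expect_equal(colnames(out), c("b", "c"))  # b: 1+1 = 2, retained
  expect_identical(unclass(remove_singletons(out)), unclass(out))
  bm <- abundance_matrix(unclass(m), "biomass")
  expect_error(remove_singletons(bm), "counts")
})

test_that("rank-biomass tables order by mean biomass per unit with id tie-breaks", {
  bm <- abundance_matrix(rbind(u1 = c(spB = 4, spA = 4, spC = 2),
                               u2 = c(spB = 6, spA = 6, spC = 0)),
                         "biomass")
  tab <- top_biomass_ranks(bm, k = 20)
  expect_equal(tab$species_id, c("spA", "spB", "spC"))  # tie at 5 broken by id
  expect_equal(tab$mean_biomass_mg, c(5, 5, 1))
  expect_equal(nrow(top_biomass_ranks(bm, k = 2)), 2)
  # pooling to one unit changes ranks only via the per-unit denominator
  pooled <- abundance_matrix(rbind(u = colSums(bm)), "biomass")
  tab_p <- top_biomass_ranks(pooled)
  expect_equal(tab_p$mean_biomass_mg, c(10, 10, 2))
  expect_equal(tab_p$species_id, tab$species_id)
})

test_that("mean_alpha averages per-sample Hill numbers", {
  m <- abundance_matrix(rbind(s1 = c(a = 1, b = 1, c = 0, d = 0),
                              s2 = c(a = 1, b = 1, c = 1, d = 1)))
  res <- mean_alpha(m, 0, B = 0)
  expect_equal(res$mean, 3)  # D = 2 and D = 4
  # q = 0 mean equals mean observed richness for random count matrices
  withr::with_seed(3, {
    mm <- matrix(rpois(40, 1), 5, 8,
                 dimnames = list(paste0("s", 1:5), paste0("sp", 1:8)))
    mm[rowSums(mm) == 0, 1] <- 1
    res0 <- mean_alpha(abundance_matrix(mm), 0, B = 0)
    expect_equal(res0$mean, mean(rowSums(mm > 0)))
  })
  # identical samples: bootstrap SE is exactly 0
  mi <- abundance_matrix(rbind(s1 = c(a = 2, b = 1), s2 = c(a = 2, b = 1)))
  expect_equal(mean_alpha(mi, 1, B = 100, seed = 2)$se, 0)
})
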