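test_that("fold_comparison applies the ratio conventions", {
  expected <- tibble::tibble(amino_acid = "Q", M = 4:6,
                             expected = c(40, 4, 0), method = "exact",
                             tail = FALSE)
  observed <- tibble::tibble(M = c(5L, 6L), count = c(50L, 3L))
  fc <- fold_comparison(observed, expected)
  expect_equal(fc$fold_ratio[fc$M == 5], 12.5)
  expect_equal(fc$fold_ratio[fc$M == 4], 0)       # 0 observed / 40 expected
  expect_true(is.infinite(fc$fold_ratio[fc$M == 6]))
  expect_true(fc$infinite[fc$M == 6])
  # zero observed with zero expected is ratio 0 by convention
  fc0 <- fold_comparison(tibble::tibble(M = 2L, count = 0L),
                         tibble::tibble(amino_acid = "Q", M = 2L,
                                        expected = 0))
  expect_equal(fc0$fold_ratio[fc0$M == 2], 0)
  expect_error(
    fold_comparison(tibble::tibble(M = 1L, count = -1L),
                    tibble::tibble(amino_acid = "Q", M = 1L, expected = 1)),
    "negative")
})

test_that("minimal_significant_length finds the smallest qualifying length", {
  tab <- tibble::tibble(M = 4:6, observed = c(8L, 22L, 30L),
                        fold_ratio = c(2, 11, 30))
  expect_equal(minimal_significant_length(tab), 5L)
  tab$fold_ratio <- c(2, 4, 8)
  expect_true(is.na(minimal_significant_length(tab)))
  # monotone in the fold threshold
  tab2 <- tibble::tibble(M = 3:8, observed = rep(5L, 6),
                         fold_ratio = c(1, 12, 9, 40, 80, 200))
  prev <- 0L
  for (thr in c(5, 10, 20, 50, 100)) {
    cur <- minimal_significant_length(tab2, fold_threshold = thr)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("association_z reproduces the published contingency worked cases", {
  # poly-L row of the human disease table
  r <- association_z(tibble::tibble(N = 59053, N_a = 2501, N_b = 1503,
                                    N_ab = 125))
  expect_equal(r$mean, 63.65, tolerance = 1e-3)
  expect_equal(r$z, 7.96, tolerance = 1e-2)
  expect_equal(r$band, "strong")
  # poly-E row lands in the moderate band
  r2 <- association_z(tibble::tibble(N = 59053, N_a = 2501, N_b = 1625,
                                     N_ab = 108))
  expect_gt(r2$z, 3); expect_lte(r2$z, 5)
  expect_equal(r2$band, "moderate")
  # exact independence has z = 0
  r3 <- association_z(tibble::tibble(N = 1000, N_a = 100, N_b = 50,
                                     N_ab = 5))
  expect_equal(r3$z, 0)
  expect_equal(r3$band, "none")
})

test_that("association_z validates counts and refuses degenerate margins", {
  expect_error(association_z(tibble::tibble(N = 100, N_a = 10, N_b = 5,
                                            N_ab = 7)), "invalid")
  expect_error(association_z(tibble::tibble(N = 100, N_a = 0, N_b = 5,
                                            N_ab = 0)), "undefined Z")
  expect_error(association_z(tibble::tibble(N = 100, N_a = 10, N_b = 100,
                                            N_ab = 10)), "undefined Z")
  # poisson alternative has the larger sd (no finite-margin shrinkage),
  # hence a smaller positive z
  cnt <- tibble::tibble(N = 59053, N_a = 2501, N_b = 1503, N_ab = 125)
  expect_lt(association_z(cnt, sd_method = "poisson")$z,
            association_z(cnt)$z)
  expect_equal(association_z(cnt, sd_method = "poisson")$sd,
               sqrt(association_z(cnt)$mean))
})

test_that("resample_enrichment is deterministic and recovers a spiked signal", {
  recs <- sample_null_proteome(2000, length_model = "fixed",
                               fixed_length = 300, seed = 21)
  sp <- spike_repeats(recs, "E", run_length = 6, fraction = 0.05, seed = 22)
  tab <- longest_run_table(sp$records)
  en <- resample_enrichment(sp$truth$protein_id, tab, seed = 5)
  e_cells <- dplyr::filter(en, amino_acid == "E", motif_length <= 6)
  expect_true(all(e_cells$z > 5))
  expect_true(all(e_cells$significant))
  en2 <- resample_enrichment(sp$truth$protein_id, tab, seed = 5)
  expect_identical(en, en2)
  expect_error(resample_enrichment(c("nope"), tab, seed = 1), "subset")
  expect_error(resample_enrichment(character(), tab, seed = 1), "non-empty")
})

test_that("degenerate resample cells are flagged, not crashed", {
  # universe where exactly one protein carries a rare repeat and is targeted
  tab <- tidyr::crossing(protein_id = paste0("u", 1:50),
                         amino_acid = AA20) |>
    dplyr::mutate(longest = ifelse(protein_id == "u1" & amino_acid == "W",
                                   9L, 0L))
  en <- resample_enrichment("u1", tab, lengths = 9, n_samples = 5, seed = 2)
  w <- dplyr::filter(en, amino_acid == "W")
  expect_true(is.infinite(w$z) || w$z > 5)
  if (is.infinite(w$z)) expect_true(w$degenerate)
  zero <- dplyr::filter(en, amino_acid == "A")
  expect_equal(zero$z, 0)
  expect_false(zero$degenerate)
})

test_that("partner_summary computes degrees with deduplication and SEM", {
  edges <- tibble::tibble(from = c("a", "a"), to = c("b", "c"))
  ps <- partner_summary(edges, list(g = "a"))
  expect_equal(ps$mean_partners[ps$group == "g"], 2)
  expect_equal(ps$sem[ps$group == "g"], 0)
  # duplicate edges in either orientation collapse; self-loops drop
  edges2 <- tibble::tibble(from = c("a", "b", "a"), to = c("b", "a", "a"))
  ps2 <- partner_summary(edges2, list(g = c("a", "b")))
  expect_equal(ps2$mean_partners[ps2$group == "g"], 1)
  # invariant to edge order
  ps3 <- partner_summary(edges2[c(3, 1, 2), ], list(g = c("a", "b")))
  expect_equal(ps2$mean_partners, ps3$mean_partners)
  expect_warning(partner_summary(edges, list(g = "a", empty = character())),
                 "skipped")
})

test_that("partner_summary recovers simulated group mean degrees", {
  ids <- sprintf("P%04d", 1:3000)
  groups <- list(Q = ids[1:300], L = ids[301:600])
  ed <- simulate_interaction_edges(ids, groups,
                                   group_means = c(Q = 30, L = 5),
                                   background_mean = 16, seed = 8)
  ps <- partner_summary(ed, groups, universe = ids)
  q <- dplyr::filter(ps, group == "Q")
  l <- dplyr::filter(ps, group == "L")
  expect_lt(abs(q$mean_partners - 30), 3 * q$sem + 0.8)
  expect_lt(abs(l$mean_partners - 5), 3 * l$sem + 0.8)
})
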