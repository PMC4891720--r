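test_that("null proteome generation is deterministic and honours the length model", {
  a <- sample_null_proteome(50, seed = 5)
  b <- sample_null_proteome(50, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_null_proteome(50, seed = 6)))

  fixed <- sample_null_proteome(10, length_model = "fixed", fixed_length = 7,
                                seed = 1)
  expect_true(all(nchar(fixed$sequence) == 7))

  lg <- sample_null_proteome(4000, seed = 2)
  lens <- nchar(lg$sequence)
  expect_true(all(lens >= 30 & lens <= 10000))
  # lognormal clamped at [30, 10000] reproduces the target moments loosely
  expect_lt(abs(mean(lens) - 395) / 395, 0.12)

  emp <- sample_null_proteome(100, length_model = "empirical",
                              length_counts = tibble::tibble(length = c(10L, 20L),
                                                             count = c(1L, 3L)),
                              seed = 3)
  expect_true(all(nchar(emp$sequence) %in% c(10L, 20L)))
})

test_that("single-letter frequency vector produces the degenerate record", {
  r <- sample_null_proteome(1, length_model = "fixed", fixed_length = 1,
                            aa_freq = c(Q = 1), seed = 1)
  expect_equal(r$sequence, "Q")
  expect_error(sample_null_proteome(5, aa_freq = c(Q = 0.5), seed = 1), "sum 1")
  expect_error(sample_null_proteome(5, aa_freq = c(J = 1), seed = 1),
               "canonical")
})

test_that("generated residue frequencies match the requested vector", {
  recs <- sample_null_proteome(2000, length_model = "fixed",
                               fixed_length = 100, seed = 5)
  prof <- profile_proteome(recs)
  expect_true(all(abs(prof$aa_frequencies$frequency - 0.05) < 0.005))
})

test_that("spike_repeats inserts the exact run at the recorded offset", {
  recs <- sample_null_proteome(200, length_model = "fixed", fixed_length = 50,
                               seed = 4)
  sp <- spike_repeats(recs, "Q", run_length = 8, fraction = 1.0, seed = 5)
  tab <- longest_run_table(sp$records)
  q <- tab$longest[tab$amino_acid == "Q"]
  expect_true(all(q >= 8))
  got <- substr(sp$records$sequence[match(sp$truth$protein_id, sp$records$id)],
                sp$truth$offset, sp$truth$offset + 7L)
  expect_true(all(got == strrep("Q", 8)))
  # insertion preserves background residues
  expect_equal(nchar(sp$records$sequence), nchar(recs$sequence) + 8L)

  sp2 <- spike_repeats(recs, "E", run_length = 3, fraction = 0.015, seed = 6)
  expect_equal(nrow(sp2$truth), ceiling(0.015 * 200))
  expect_error(spike_repeats(recs, "Q", 8, fraction = 0, seed = 1), "fraction")
})

test_that("disease labels reflect the requested relative risk", {
  ids <- sprintf("P%05d", 1:20000)
  targets <- ids[1:1000]
  lab <- simulate_disease_labels(ids, targets, base_rate = 0.04,
                                 relative_risk = 2, seed = 7)
  expect_identical(lab, simulate_disease_labels(ids, targets, 0.04, 2, seed = 7))
  in_t <- mean(lab$label[lab$id %in% targets])
  out_t <- mean(lab$label[!lab$id %in% targets])
  expect_lt(abs(in_t - 0.08), 0.025)
  expect_lt(abs(out_t - 0.04), 0.006)

  none <- simulate_disease_labels(ids, targets, base_rate = 0,
                                  relative_risk = 5, seed = 8)
  expect_true(all(none$label == 0))
  expect_error(simulate_disease_labels(ids, targets, 0.6, 2, seed = 1),
               "\\[0, 1\\]")
  expect_error(simulate_disease_labels(ids, c("zz"), 0.1, 1, seed = 1),
               "subset")
})

test_that("null relative risk gives no association; elevated risk is detected", {
  # margins sized to the human disease table: 1500 repeat-bearing targets
  # in a 59,000-protein proteome, 4% baseline disease rate
  ids <- sprintf("P%05d", 1:59000)
  targets <- ids[1:1500]
  z_of <- function(rr, seed) {
    lab <- simulate_disease_labels(ids, targets, 0.04, rr, seed = seed)
    flagged <- lab$id[lab$label == 1]
    association_z(tibble::tibble(
      N = length(ids), N_a = length(flagged), N_b = length(targets),
      N_ab = sum(targets %in% flagged)))$z
  }
  z_null <- vapply(1:100, function(s) z_of(1, s), numeric(1))
  expect_gte(mean(abs(z_null) < 3), 0.95)
  z_alt <- vapply(1:100, function(s) z_of(2, 500 + s), numeric(1))
  expect_gte(mean(z_alt > 5), 0.95)
})

test_that("interaction edge simulation hits the background mean degree", {
  ids <- sprintf("P%04d", 1:5000)
  ed <- simulate_interaction_edges(ids, background_mean = 16, seed = 9)
  expect_identical(ed, simulate_interaction_edges(ids, background_mean = 16,
                                                  seed = 9))
  deg <- table(factor(c(ed$from, ed$to), levels = ids))
  expect_lt(abs(mean(deg) - 16), 1)
  expect_true(all(ed$from != ed$to))
  expect_false(any(duplicated(paste(ed$from, ed$to))))
  expect_error(
    simulate_interaction_edges(ids, groups = list(g = "missing"),
                               group_means = c(g = 3), seed = 1),
    "unknown group member")
})

test_that("a zero-mean group receives no stubs of its own", {
  ids <- sprintf("P%03d", 1:200)
  ed <- simulate_interaction_edges(ids, groups = list(iso = ids[1:20]),
                                   group_means = c(iso = 0),
                                   background_mean = 4, seed = 10)
  deg <- table(factor(c(ed$from, ed$to), levels = ids))
  expect_true(all(deg[1:20] == 0))
})
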