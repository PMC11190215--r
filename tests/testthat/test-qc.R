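test_that("completeness check names each missing required frequency", {
  expect_equal(nrow(check_completeness(clean_audiogram(), 1)), 0)
  no_air2k <- make_audiogram(c(20, 20, 20, 20, NA, 20, 20), rep(15, 5))
  r <- check_completeness(no_air2k, 1)
  expect_equal(r$code, "missing_frequency")
  expect_equal(r$conduction, "air")
  expect_equal(r$freq, 2000)
  # 250 Hz bone is optional but 500 Hz is required
  b <- make_audiogram(rep(20, 7), c(15, NA, 15, 15, 15))
  r <- check_completeness(b, 1)
  expect_equal(r[, c("conduction", "freq")],
               data.frame(conduction = "bone", freq = 500))
})

test_that("air range check applies the 90 dB low-frequency limit", {
  hot <- make_audiogram(c(20, 20, 20, 115, 20, 20, 20), rep(15, 5))
  r <- check_air_range(hot, 1)
  expect_equal(r$code, "air_out_of_range")
  expect_equal(r$freq, 1000)
  low <- make_audiogram(c(20, 95, 20, 20, 20, 20, 20), rep(15, 5))
  expect_equal(check_air_range(low, 1)$freq, 250)
  at_limit <- make_audiogram(c(90, 90, 110, 110, 110, 110, 110), rep(15, 5))
  expect_equal(nrow(check_air_range(at_limit, 1)), 0)
  neg <- make_audiogram(c(20, 20, -15, 20, 20, 20, 20), rep(15, 5))
  expect_equal(check_air_range(neg, 1)$freq, 500)
  zeros <- make_audiogram(rep(0, 7), rep(0, 5))
  expect_equal(nrow(check_air_range(zeros, 1)), 0)
  # opposite reading of the ambiguous clause is selectable
  cfg <- qc_config(low_freq_strict = FALSE)
  expect_equal(nrow(check_air_range(low, 1, cfg)), 0)
  expect_equal(check_air_range(make_audiogram(c(20, 20, 95, 20, 20, 20, 20),
                                              rep(15, 5)), 1, cfg)$freq, 500)
})

test_that("adjacent-octave step rule is symmetric and inclusive at 30 dB", {
  jump <- make_audiogram(c(20, 20, 20, 20, 55, 55, 55), rep(15, 5))
  r <- check_air_steps(jump, 1)
  expect_equal(r$code, "air_step_violation")
  expect_equal(r$freq, 2000)   # AC(2000)=55 vs AC(1000)=20, delta 35
  at_bound <- make_audiogram(c(20, 20, 20, 20, 50, 50, 50), rep(15, 5))
  expect_equal(nrow(check_air_steps(at_bound, 1)), 0)
  falling <- make_audiogram(c(60, 60, 60, 60, 25, 25, 25), rep(15, 5))
  expect_equal(check_air_steps(falling, 1)$freq, 2000)
  flat <- flat_audiogram(40, 5)
  expect_equal(nrow(check_air_steps(flat, 1)), 0)
})

test_that("bone range check applies the 40 dB limit at 250 Hz", {
  hot <- make_audiogram(rep(60, 7), c(15, 15, 65, 15, 15))
  r <- check_bone_range(hot, 1)
  expect_equal(r$code, "bone_out_of_range")
  expect_equal(r$freq, 1000)
  low <- make_audiogram(rep(50, 7), c(45, 15, 15, 15, 15))
  expect_equal(check_bone_range(low, 1)$freq, 250)
  fine <- make_audiogram(rep(60, 7), c(40, 60, 60, 60, 60))
  expect_equal(nrow(check_bone_range(fine, 1)), 0)
  tens <- make_audiogram(rep(20, 7), rep(10, 5))
  expect_equal(nrow(check_bone_range(tens, 1)), 0)
})

test_that("air-bone relation bounds the signed gap in [-10, 50]", {
  big_gap <- make_audiogram(rep(70, 7), c(10, 10, 10, 10, 10))
  r <- check_air_bone_relation(big_gap, 1)
  expect_equal(r$code, rep("air_bone_relation", 5))
  expect_equal(r$value, rep(60, 5))
  bone_over <- make_audiogram(rep(20, 7), c(20, 20, 35, 20, 20))
  r <- check_air_bone_relation(bone_over, 1)
  expect_equal(r$freq, 1000)
  expect_equal(r$value, -15)
  equal_curves <- flat_audiogram(30, 0)
  expect_equal(nrow(check_air_bone_relation(equal_curves, 1)), 0)
  at_bounds <- make_audiogram(rep(50, 7), c(60, 0, 0, 0, 0))  # gaps -10, 50
  expect_equal(nrow(check_air_bone_relation(at_bounds, 1)), 0)
})

test_that("six-record fixture: one violation per rule plus one clean", {
  fixture <- bind_audiograms(
    make_audiogram(c(20, 20, 20, 20, NA, 20, 20), rep(15, 5), id = "miss"),
    make_audiogram(c(90, 95, 80, 60, 50, 40, 30), c(NA, 60, 55, 45, 35),
                   id = "air_rng"),
    make_audiogram(c(20, 20, 20, 20, 55, 55, 55), rep(15, 5), id = "step"),
    make_audiogram(rep(60, 7), c(15, 15, 65, 15, 15), id = "bone_rng"),
    make_audiogram(rep(70, 7), rep(10, 5), id = "relation"),
    clean_audiogram(id = "clean"))
  rep <- apply_qc(fixture)
  expect_equal(nrow(rep$kept), 1)
  expect_equal(rep$kept$subject_id, "clean")
  expect_equal(nrow(rep$rejected), 5)
  expect_equal(unname(rep$counts),
               c(1L, 1L, 1L, 1L, 1L))
  for (i in seq_len(5)) {
    codes <- unique(rep$reasons[[i]]$code)
    expect_length(codes, 1)
  }
  expect_equal(rep$counts[["missing_frequency"]], 1L)
  expect_equal(rep$counts[["air_bone_relation"]], 1L)
})

test_that("apply_qc keeps clean sets, handles empty input, preserves order", {
  clean <- bind_audiograms(clean_audiogram("a"), flat_audiogram(50, 20, "b"),
                           flat_audiogram(0, 0, "c"))
  rep <- apply_qc(clean)
  expect_equal(rep$kept$subject_id, c("a", "b", "c"))
  expect_equal(nrow(rep$rejected), 0)
  empty <- clean[0, ]
  rep0 <- apply_qc(empty)
  expect_equal(rep0$n_input, 0)
  expect_equal(nrow(rep0$kept), 0)
})

test_that("apply_qc equals the conjunction of the five checks (randomized)", {
  set.seed(421)
  n <- 120
  ac <- matrix(5 * round(runif(n * 7, -4, 25)), n, 7)
  bc <- matrix(5 * round(runif(n * 5, -4, 14)), n, 5)
  ac[runif(n * 7) < 0.06] <- NA
  bc[runif(n * 5) < 0.06] <- NA
  set <- audiogram_set(sprintf("r%03d", 1:n),
                       rep("left", n), ac, bc)
  rep <- apply_qc(set)
  brute <- vapply(seq_len(n), function(i) {
    nrow(check_completeness(set, i)) == 0 &&
      nrow(check_air_range(set, i)) == 0 &&
      nrow(check_air_steps(set, i)) == 0 &&
      nrow(check_bone_range(set, i)) == 0 &&
      nrow(check_air_bone_relation(set, i)) == 0
  }, logical(1))
  expect_equal(set$subject_id[brute], rep$kept$subject_id)
  expect_equal(rep$n_input, nrow(rep$kept) + nrow(rep$rejected))
})

test_that("adding a violation never rescues a kept record (monotonicity)", {
  base <- clean_audiogram()
  expect_equal(nrow(apply_qc(base)$rejected), 0)
  worse <- base
  worse$ac_1000 <- 115
  expect_equal(nrow(apply_qc(worse)$kept), 0)
  worse2 <- base
  worse2$bc_2000 <- NA
  expect_equal(nrow(apply_qc(worse2)$kept), 0)
})
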