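profile_with_generic <- function(id, generic, scores, start = 1L) {
  res <- toy_residues(length(generic), start = start)
  res$generic_number <- generic
  structure(list(receptor_id = id, residues = res, omega0 = 1,
                 scores = scores, disconnects = logical(length(scores))),
            class = "bridging_profile")
}

test_that("profiles align on the intersection of shared generic positions", {
  p1 <- profile_with_generic("r1", c("3x50", "6x44", "7x52"), c(1, 2, 3))
  p2 <- profile_with_generic("r2", c("3x50", "6x44"), c(4, 5))
  tab <- align_profiles(list(p1, p2))
  expect_equal(rownames(tab), c("3x50", "6x44"))
  expect_equal(unname(tab[, "r1"]), c(1, 2))
  expect_equal(unname(tab[, "r2"]), c(4, 5))

  # whitelist restriction removes shared-but-unlisted positions
  tab2 <- align_profiles(list(p1, p2), whitelist = c("6x44"))
  expect_equal(rownames(tab2), "6x44")

  # single profile: identity restricted to the whitelist
  tab3 <- align_profiles(list(p1), whitelist = c("7x52", "3x50"))
  expect_equal(unname(tab3[, 1]), c(3, 1))

  dup <- profile_with_generic("r3", c("3x50", "3x50"), c(1, 2))
  expect_error(align_profiles(list(dup)), "multiple residues")
})

test_that("the packaged transmembrane whitelist skips 7x44", {
  wl <- default_whitelist()
  expect_true("7x43" %in% wl)
  expect_true("7x45" %in% wl)
  expect_false("7x44" %in% wl)
  expect_true(all(grepl("^[1-7]x[0-9]{2}$", wl)))
  # band sizes: 21+24+31+20+23+24+8+11
  expect_length(wl, 162)
})

test_that("averaging is an unweighted mean with population-sd error bars", {
  p1 <- profile_with_generic("r1", c("3x50", "6x44"), c(1, 1))
  p2 <- profile_with_generic("r2", c("3x50", "6x44"), c(3, 1))
  avg <- average_profile(align_profiles(list(p1, p2)))
  expect_equal(avg$mean_score, c(2, 1))
  expect_equal(avg$error, c(1, 0))
  expect_equal(avg$n_contributors, c(2, 2))

  # commutes with receptor reordering
  avg2 <- average_profile(align_profiles(list(p2, p1)))
  expect_equal(avg2$mean_score, avg$mean_score)
  expect_equal(avg2$error, avg$error)
})

test_that("active-inactive pairing enumerates pairs and bounds errors", {
  fx <- make_hinge_ensemble(c(10, 10), max_angle = 10, noise_sd = 0.2,
                            n_members = 2, seed = 21)
  se <- make_state_ensemble(fx, n_active = 1, n_inactive = 1,
                            state_angle_offset = 25, seed = 3)
  one <- pair_error_profile(se$ensemble)
  expect_equal(one$n_pairs, 1)
  expect_equal(one$error, rep(0, 20))

  se2 <- make_state_ensemble(fx, n_active = 2, n_inactive = 3,
                             state_angle_offset = 25, seed = 3)
  six <- pair_error_profile(se2$ensemble)
  expect_equal(six$n_pairs, 6)
  expect_equal(ncol(six$pair_scores), 6)

  # partially active members are excluded by default, usable on request
  ens3 <- se2$ensemble
  ens3$members$state_label[ens3$members$state_label == "active"] <-
    "partially_active"
  expect_error(pair_error_profile(ens3), "at least one active")
  expect_equal(pair_error_profile(ens3, partial_as_active = TRUE)$n_pairs, 6)
})

test_that("pair errors stay below the profile's peak-to-trough variation", {
  fx <- make_hinge_ensemble(c(15, 15), max_angle = 10, noise_sd = 0.2,
                            n_members = 2, seed = 6)
  se <- make_state_ensemble(fx, n_active = 3, n_inactive = 3,
                            state_angle_offset = 30, seed = 6)
  pe <- pair_error_profile(se$ensemble)
  expect_lt(mean(pe$error), diff(range(pe$mean_scores)))
})

test_that("full-ensemble and mean pair-profiles agree on two-state fixtures", {
  cors <- vapply(0:4, function(s) {
    fx <- make_hinge_ensemble(c(30, 30), max_angle = 10, noise_sd = 0.2,
                              n_members = 2, seed = 100 + s)
    se <- make_state_ensemble(fx, n_active = 3, n_inactive = 3,
                              state_angle_offset = 30, seed = s)
    full <- ensemble_profile(se$ensemble)
    pe <- pair_error_profile(se$ensemble)
    pearson_correlation(full$scores, pe$mean_scores)
  }, numeric(1))
  expect_true(all(cors > 0.7))
})

test_that("pearson correlation matches the product-moment formula and its
           invariances", {
  p <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(p, p), 1.0)
  expect_equal(pearson_correlation(p, -2 * p + 7), -1.0)

  q <- c(1, 2, 3, 100)
  hand <- sum((p - mean(p)) * (q - mean(q))) /
    sqrt(sum((p - mean(p))^2) * sum((q - mean(q))^2))
  expect_equal(pearson_correlation(p, q), hand)

  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  expect_lt(abs(pearson_correlation(3 * a + 1, b) -
                  pearson_correlation(a, b)), 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
})
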