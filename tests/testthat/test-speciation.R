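test_that("histogram densities follow the definition and conserve counts", {
  d <- histogram_to_density(c(5), c(10, 20))
  expect_equal(d$density, 0.5)
  expect_equal(d$support, sqrt(200))
  z <- histogram_to_density(rep(0, 4), c(1, 2, 4, 8, 16))
  expect_equal(z$density, rep(0, 4))
  set.seed(1)
  cts <- rpois(19, 30)
  edges <- instrument_config()$bin_edges
  dc <- histogram_to_density(cts, edges)
  expect_equal(sum(dc$density * diff(edges)), sum(cts), tolerance = 1e-9)
})

test_that("identical channels give unit speciation indices and signatures", {
  edges <- instrument_config()$bin_edges
  cts <- c(0, 0, 2, 10, 40, 80, 40, 10, 2, rep(0, 10))
  d1 <- histogram_to_density(cts, edges)
  F1 <- edges[6]  # lower bound of the modal bin
  s <- speciation_index(d1, d1, F1)
  expect_equal(as.numeric(s), 1, tolerance = 1e-12)
  sig <- optical_signature(rbind(cts, cts, cts, cts), edges)
  expect_true(sig$valid)
  expect_equal(unname(sig$signature), rep(1, 6), tolerance = 1e-12)
  expect_equal(sig$F1, edges[5])  # flank policy: one populated bin below mode
})

test_that("a pure gain shift on geometric bins inverts to 1/gain", {
  cfg <- octave_config()  # intensity edge ratio exactly 2
  edges <- cfg$bin_edges
  cts <- c(0, 0, 0, 2, 10, 40, 80, 40, 10, 2, rep(0, 9))
  shift <- function(x, m) c(rep(0, m), x)[seq_along(x)]
  d1 <- histogram_to_density(cts, edges)
  F1 <- edges[which.max(cts)]
  for (m in 1:3) {   # gains 2, 4, 8: counts shifted m bins up
    dc <- histogram_to_density(shift(cts, m), edges)
    s <- as.numeric(speciation_index(d1, dc, F1))
    expect_equal(s, 1 / 2^m, tolerance = 1e-9)
  }
  # and as a full signature: gains (2, 4, 8) -> (1/2, 1/4, 1/8, 2, 4, 2)
  counts4 <- rbind(cts, shift(cts, 1), shift(cts, 2), shift(cts, 3))
  sig <- optical_signature(counts4, edges)
  expect_true(sig$valid)
  expect_equal(unname(sig$signature), c(1/2, 1/4, 1/8, 2, 4, 2),
               tolerance = 1e-9)
})

test_that("the inversion matches the fine-grid oracle on toy histograms", {
  edges <- c(1, 2, 4, 8, 16)
  d1 <- histogram_to_density(c(0, 40, 10, 0), edges)
  dc <- histogram_to_density(c(0, 10, 40, 0), edges)
  got <- as.numeric(speciation_index(d1, dc, F1 = 2))
  want <- speciation_brute(edges, c(0, 40, 10, 0), edges, c(0, 10, 40, 0), 2)
  expect_equal(got, want, tolerance = 1e-6)
  # closed form: both polylines are single log-log segments of slope -2/+2;
  # matching F * dN/dF at F1 = 2 lands on the rising branch at Fc = 8
  expect_equal(got, 0.25, tolerance = 1e-9)

  # randomized toys with up to 6 bins
  set.seed(33)
  n_checked <- 0
  for (rep in 1:40) {
    nb <- sample(3:6, 1)
    edges <- 2^(0:nb)
    c1 <- rpois(nb, 15) + c(0, rep(1, nb - 2), 0)
    cc <- rpois(nb, 15) + c(0, rep(1, nb - 2), 0)
    F1 <- edges[which.max(c1)]
    d1 <- histogram_to_density(c1, edges)
    dcur <- histogram_to_density(cc, edges)
    got <- tryCatch(as.numeric(speciation_index(d1, dcur, F1)),
                    speciation_error = function(e) NA_real_)
    want <- tryCatch(speciation_brute(edges, c1, edges, cc, F1),
                     error = function(e) NA_real_)
    if (!is.na(got) && !is.na(want)) {
      expect_equal(got, want, tolerance = 1e-6)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("out-of-range inversions are flagged errors, not extrapolations", {
  edges <- c(1, 2, 4, 8, 16)
  d1 <- histogram_to_density(c(0, 40, 10, 0), edges)
  weak <- histogram_to_density(c(0, 2, 1, 0), edges)  # max density too low
  expect_error(speciation_index(d1, weak, 2), class = "speciation_out_of_range")
  expect_error(speciation_index(d1, d1, 100), class = "speciation_out_of_range")
  empty <- histogram_to_density(c(0, 1, 0, 0), edges)
  expect_error(speciation_index(d1, empty, 2), class = "speciation_no_signal")
  sig <- optical_signature(rbind(c(0, 40, 10, 0), c(0, 2, 1, 0),
                                 c(0, 40, 10, 0), c(0, 40, 10, 0)), edges)
  expect_false(sig$valid)
  expect_equal(sig$failed_channel, 2L)
  expect_true(all(is.na(sig$signature)))
})

test_that("ratio entries equal the quotients of the index entries", {
  cfg <- instrument_config()
  pr <- species_profile("t", 28, c(1.3, 0.8, 0.5), mean_rate = 5000)
  set.seed(8)
  f <- simulate_frame(pr, no_contamination(), cfg)
  sig <- optical_signature(f, cfg$bin_edges)
  expect_true(sig$valid)
  s <- sig$signature
  expect_equal(s[["S2_over_S3"]], s[["S2"]] / s[["S3"]], tolerance = 1e-12)
  expect_equal(s[["S2_over_S4"]], s[["S2"]] / s[["S4"]], tolerance = 1e-12)
  expect_equal(s[["S3_over_S4"]], s[["S3"]] / s[["S4"]], tolerance = 1e-12)
})

test_that("signatures are stable against the choice of adjacent F1 bins", {
  cfg <- instrument_config()
  pr <- species_profile("t", 28, c(1.3, 0.8, 0.5), mean_rate = 20000)
  set.seed(15)
  f <- simulate_frame(pr, no_contamination(), cfg)
  cts <- unclass(f)
  modal <- which.max(cts[1, ])
  sigs <- lapply(c(modal - 1, modal, modal + 1), function(b) {
    optical_signature(cts, cfg$bin_edges, F1 = cfg$bin_edges[b])
  })
  expect_true(all(vapply(sigs, `[[`, TRUE, "valid")))
  S <- t(vapply(sigs, function(s) s$signature[1:3], numeric(3)))
  drift <- apply(S, 2, function(col) max(abs(col / col[2] - 1)))
  expect_lt(max(drift), 0.10)
})

test_that("gain covariance holds on densely populated simulated histograms", {
  cfg <- octave_config()
  # broad size distribution so the density curves span several octaves and
  # the gained curves stay invertible
  base <- species_profile("g1", 28, c(1, 1, 1), mean_rate = 50000, gsd = 1.6)
  gained <- species_profile("g2", 28, c(2, 4, 8), mean_rate = 50000, gsd = 1.6)
  set.seed(23)
  f1 <- simulate_frame(base, no_contamination(), cfg, channel_noise = 0.05)
  set.seed(23)
  f2 <- simulate_frame(gained, no_contamination(), cfg, channel_noise = 0.05)
  s1 <- optical_signature(f1, cfg$bin_edges)
  s2 <- optical_signature(f2, cfg$bin_edges)
  expect_true(s1$valid && s2$valid)
  for (i in 1:3) {
    g <- c(2, 4, 8)[i]
    expect_equal(s2$signature[[i]] / s1$signature[[i]], 1 / g,
                 tolerance = 0.02 / 1)
  }
})

test_that("signature tables carry one row per cumulative distribution", {
  cfg <- instrument_config()
  pr <- builtin_profiles()[["Betula pendula"]]
  ses <- simulate_session(pr, no_contamination(), 60, cfg, seed = 41)
  ov <- oversample_cumulative(ses$frames, n_draws = 8, seed = 41)
  tab <- signature_table(ov$counts, cfg$bin_edges,
                         species = rep("Betula pendula", 8))
  expect_equal(nrow(tab), 8L)
  # flat-topped peaks occasionally put F1 at the density maximum and the
  # inversion rightly refuses them; most rows must still be valid
  expect_gte(mean(tab$valid), 0.75)
  expect_true(all(tab$S2[tab$valid] > 0))
  expect_true(all(is.na(tab$S2[!tab$valid])))
  tab_all <- signature_table(ov$counts[1:2, , drop = FALSE], cfg$bin_edges,
                             f1_policy = "all_bins")
  expect_gt(nrow(tab_all), 2L)  # one row per well-populated sizing bin
})
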