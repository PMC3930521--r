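test_that("Tajima's D matches direct evaluation of the published constants", {
  # independent inline evaluation for n = 10, S = 5, theta_pi = 1.5
  n <- 10; S <- 5; tp <- 1.5
  a1 <- sum(1 / 1:9); a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (tp - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(tajima_d_value(10, 5, 1.5), expected, tolerance = 1e-12)
  expect_equal(tajima_d_value(10, 5, 1.5), -0.607, tolerance = 1e-3)
})

test_that("Tajima's D on an alignment uses its S and theta_pi", {
  aln <- alignment(paste0("s", 1:6),
                   c("AAAA", "AAAA", "AAAT", "AATT", "AAAA", "TAAA"))
  res <- tajimas_d(aln, n_sim = 0)
  expect_equal(res$S, 3)
  expect_equal(res$theta_pi, nucleotide_diversity(aln, per_site = FALSE))
  expect_equal(res$D, tajima_d_value(6, res$S, res$theta_pi))
})

test_that("Fu's F_S matches exact Ewens enumeration", {
  expect_equal(fus_fs(4, 3, 1), log(7 / 17), tolerance = 1e-10)
  # log-space Stirling recurrence vs exact rational enumeration, n <= 12
  for (n in c(5, 8, 12)) {
    for (theta in c(0.5, 2)) {
      for (k_obs in c(2, ceiling(n / 2), n)) {
        probs <- vapply(1:n, function(k) ewens_pr_k(n, k, theta), 0)
        sp <- sum(probs[k_obs:n])
        expect_equal(fus_fs(n, k_obs, theta), log(sp / (1 - sp)),
                     tolerance = 1e-10)
      }
    }
  }
  expect_warning(fs1 <- fus_fs(6, 1, 1), "Inf")
  expect_true(is.infinite(fs1))
  # maximal haplotype count with tiny theta is strongly negative
  expect_lt(fus_fs(10, 10, 0.1), -20)
})

test_that("neutral constant-size simulations centre Tajima's D near zero", {
  set.seed(100)
  d <- replicate(300, {
    sm <- geelbek:::tree_summaries(geelbek:::sim_coalescent_tree(15, 4))
    if (sm$S < 1) NA_real_ else tajima_d_value(15, sm$S, sm$pi)
  })
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.2)
})

test_that("star-like expansions drive D and F_S negative on average", {
  set.seed(101)
  stats <- replicate(200, {
    sm <- geelbek:::tree_summaries(
      geelbek:::sim_coalescent_tree(20, 10, sizes = c(1, 0.005), breaks = 3))
    c(D = if (sm$S < 1) NA_real_ else tajima_d_value(20, sm$S, sm$pi),
      FS = if (sm$pi <= 0 || sm$k < 2) NA_real_ else fus_fs(20, sm$k, sm$pi))
  })
  expect_lt(mean(stats["D", ], na.rm = TRUE), -0.3)
  expect_lt(mean(stats["FS", ], na.rm = TRUE), -1)
})

test_that("mismatch histogram matches hand-counted pair differences", {
  two <- alignment(c("a", "b"), c("AAAA", "ATTA"))
  mm2 <- mismatch_observed(two)
  expect_equal(mm2$count, c(0, 0, 1))       # single pair, 2 differences

  aln <- alignment(paste0("s", 1:4), c("AAAA", "AAAT", "AATT", "AAAA"))
  # pairs: 12:1 13:2 14:0 23:1 24:1 34:2
  mm <- mismatch_observed(aln)
  expect_equal(mm$count, c(1, 3, 2))
  expect_equal(sum(mm$freq), 1)

  same <- alignment(c("a", "b", "c"), rep("ACGT", 3))
  expect_equal(mismatch_observed(same)$count, 3)  # point mass at zero
})

test_that("expected mismatch curve is a proper distribution with the right limits", {
  j <- 0:400
  f <- expected_mismatch(j, tau = 2.5, theta0 = 1.2, theta1 = 7.3)
  expect_equal(sum(f), 1, tolerance = 1e-8)
  expect_true(all(f >= 0))
  # tau = 0: equilibrium geometric-like curve with mean theta0
  f0 <- expected_mismatch(j, 0, 2, 50)
  expect_equal(sum(j * f0), 2, tolerance = 1e-8)
  expect_equal(f0[1:5], 2^(0:4) / 3^(1:5), tolerance = 1e-10)
  # mean grows with tau towards the theta1 regime
  means <- vapply(c(0, 2, 5), function(tt) {
    ff <- expected_mismatch(j, tt, 1, 20); sum(j * ff)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("least-squares fit recovers parameters of a clean model curve", {
  j <- 0:40
  f <- expected_mismatch(j, tau = 3, theta0 = 1, theta1 = 20)
  fit <- fit_sudden_expansion(f, n = 50, n_boot = 0)
  expect_equal(fit$tau, 3, tolerance = 0.05)
  expect_equal(fit$theta0, 1, tolerance = 0.1)
  expect_equal(fit$theta1, 20, tolerance = 0.15)
  expect_lt(fit$ssd, 1e-8)
  expect_true(fit$theta0 <= fit$theta1)
})

test_that("time conversion is linear in tau and inverse in rate and length", {
  clock <- clock_config(rate = 3.6, L = 583, gen_time = 2.2)
  expect_equal(time_since_expansion(0, clock)$t_years, 0)
  t1 <- time_since_expansion(1, clock)$t_years
  expect_equal(time_since_expansion(2, clock)$t_years, 2 * t1)
  expect_equal(time_since_expansion(1, clock_config(7.2, 583, 2.2))$t_years,
               t1 / 2)
  expect_equal(time_since_expansion(1, clock_config(3.6, 1166, 2.2))$t_years,
               t1 / 2)
  # u = 0.5 per year and tau = 1 -> one year
  expect_equal(time_since_expansion(1, clock_config(rate = 5e7, L = 1,
                                                    gen_time = 1))$t_years,
               1, tolerance = 1e-12)
  res <- time_since_expansion(2.492, clock, tau_ci = c(0.63, 8.02))
  expect_equal(res$t_generations,
               2.492 / (2 * 0.036e-6 * 583) / 2.2, tolerance = 1e-9)
  expect_true(res$t_years_low < res$t_years & res$t_years < res$t_years_high)
})

test_that("sampler rate conversions follow theta = x Ne mu and M = m / mu", {
  expect_equal(rate_conversions(0.004, 0, 4, 1e-4)$ne, 10)
  expect_equal(rate_conversions(0.004, 0, 4, 1e-4)$migrants_xnem, 0)
  rc <- rate_conversions(1, 100, 1, 1e-5)
  expect_equal(rc$m, 1e-3)
  expect_equal(rc$migrants_xnem, 100)
  expect_error(rate_conversions(1, 1, 1, 0), "mu")
})

test_that("net-divergence dating subtracts within-group diversity", {
  expect_equal(net_divergence_time(0.05, 0.008, 0.008, 3.6)$t_my,
               0.042 / 0.036, tolerance = 1e-9)
  expect_equal(net_divergence_time(0.01, 0.01, 0.01, 3.6)$t_my, 0)
  expect_warning(res <- net_divergence_time(0.005, 0.01, 0.01, 3.6), "clamped")
  expect_true(res$flagged)
  expect_equal(res$t_my, 0)
})
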