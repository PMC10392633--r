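test_that("events aggregate to per-cell records", {
  ev <- data.frame(
    cell_id = "c1", condition = "control", mode = "SCA",
    peak_time_s = 1:3, i_max_pA = c(5, 6, 7),
    charge_fC = c(10, 20, 30), molecules = c(100, 200, 300),
    t_half_ms = c(2, 3, 4), t_rise_ms = c(1, 1, 1), t_fall_ms = c(2, 2, 2),
    shape_flagged = FALSE, stringsAsFactors = FALSE
  )
  cells <- aggregate_cells(ev)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$n_events, 3)
  expect_equal(cells$mean_molecules, 200)
  expect_equal(cells$median_molecules, 200)
  # flagged events are excluded from shape summaries but kept for counts
  ev$shape_flagged[2] <- TRUE
  ev$t_half_ms[2] <- NA
  cells2 <- aggregate_cells(ev)
  expect_equal(cells2$n_events, 3)
  expect_equal(cells2$mean_t_half_ms, 3)       # mean of 2 and 4
  expect_equal(cells2$mean_molecules, 200)     # molecules keep all events
  # empty input -> empty table
  expect_equal(nrow(aggregate_cells(ev[0, ])), 0)
  # same cell_id under different conditions stays separate
  ev2 <- rbind(ev, transform(ev, condition = "OGDR"))
  expect_equal(nrow(aggregate_cells(ev2)), 2)
})

test_that("group summary is mean +/- SEM", {
  gs <- group_summary(c(10, 20, 30))
  expect_equal(gs$mean, 20)
  expect_equal(gs$sem, sd(c(10, 20, 30)) / sqrt(3))
  expect_equal(round(gs$sem, 2), 5.77)
  expect_equal(group_summary(c(4, 4, 4, 4))$sem, 0)
  expect_error(group_summary(5), "at least 2")
})

test_that("fraction of release reproduces the published worked examples", {
  expect_equal(fraction_of_release(105000, 176000)$percent_rounded, 60)
  expect_equal(fraction_of_release(208000, 299000)$percent_rounded, 70)
  expect_equal(fraction_of_release(103000, 126000)$percent_rounded, 82)
  expect_equal(fraction_of_release(116000, 205000)$percent_rounded, 57)
  expect_equal(fraction_of_release(5, 5)$percent, 100)
  # scale invariance
  expect_equal(fraction_of_release(3.3e4, 5.5e4)$percent,
               fraction_of_release(3.3e7, 5.5e7)$percent)
  expect_error(fraction_of_release(1, 0), "positive")
})

test_that("Mann-Whitney matches hand-worked examples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")
  # identical samples: ties force the approximation, p = 1 by symmetry
  mw2 <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_equal(mw2$p_value, 1)
  expect_equal(mw2$method, "normal-approximation")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("U statistics of the two one-sided tests sum to n1*n2", {
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- rnorm(sample(2:8, 1))
      b <- rnorm(sample(2:8, 1))
      u_ab <- mann_whitney(a, b)$U
      u_ba <- mann_whitney(b, a)$U
      expect_equal(u_ab + u_ba, length(a) * length(b))
    }
  })
})

test_that("exact p-values agree with brute-force enumeration and wilcox.test", {
  withr::with_seed(31, {
    for (i in 1:15) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      a <- rnorm(n1); b <- rnorm(n2)
      mw <- mann_whitney(a, b)
      expect_equal(mw$method, "exact")
      expect_equal(mw$p_value, enumerate_mw_p(a, b))
      expect_equal(mw$p_value,
                   wilcox.test(a, b, exact = TRUE)$p.value)
    }
  })
})

test_that("large or tied samples use the corrected normal approximation", {
  withr::with_seed(41, {
    a <- rnorm(25); b <- rnorm(25) + 0.8       # n1*n2 = 625 > 400
    mw <- mann_whitney(a, b)
    expect_equal(mw$method, "normal-approximation")
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_equal(mw$p_value, ref)
    # ties: compare against wilcox.test's tie-corrected approximation
    at <- round(rnorm(10), 0); bt <- round(rnorm(10) + 1, 0)
    mwt <- mann_whitney(at, bt)
    expect_equal(mwt$method, "normal-approximation")
    expect_equal(mwt$p_value,
                 suppressWarnings(wilcox.test(at, bt, exact = FALSE,
                                              correct = TRUE)$p.value))
  })
})

test_that("bootstrap CI of the fraction is ordered, deterministic and calibrated", {
  # degenerate: constant groups give a zero-width CI at the point value
  ci0 <- fraction_bootstrap_ci(rep(50, 8), rep(100, 8), n_boot = 200, seed = 1)
  expect_equal(ci0$lower, 50)
  expect_equal(ci0$upper, 50)
  expect_equal(ci0$point, 50)
  # ordering and determinism
  withr::with_seed(51, {
    rel <- rlnorm(20, log(1e5), 0.2)
    sto <- rlnorm(20, log(1.8e5), 0.2)
  })
  ci1 <- fraction_bootstrap_ci(rel, sto, n_boot = 500, seed = 9)
  ci2 <- fraction_bootstrap_ci(rel, sto, n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$point)
  expect_lte(ci1$point, ci1$upper)
  # coverage of the true ratio over replicate experiments ~ 95%
  true_ratio <- 100 * exp(log(1e5) + 0.02) / exp(log(1.8e5) + 0.02)
  hits <- withr::with_seed(61, {
    vapply(1:200, function(i) {
      r <- rlnorm(20, log(1e5), 0.2)
      s <- rlnorm(20, log(1.8e5), 0.2)
      ci <- fraction_bootstrap_ci(r, s, n_boot = 400, seed = i)
      ci$lower <= true_ratio && true_ratio <= ci$upper
    }, logical(1))
  })
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 1)
})

test_that("pairwise comparisons cover every condition pair", {
  withr::with_seed(71, {
    cells <- data.frame(
      cell_id = rep(sprintf("c%02d", 1:10), 3),
      condition = rep(c("control", "OGDR", "zinc"), each = 10),
      mode = "SCA",
      mean_molecules = c(rnorm(10, 100), rnorm(10, 200), rnorm(10, 100)),
      stringsAsFactors = FALSE
    )
  })
  out <- compare_groups(cells, parameters = "mean_molecules")
  expect_equal(nrow(out), 3)                   # 3 pairs
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  big <- out[out$group_a == "control" & out$group_b == "OGDR", ]
  expect_lt(big$p_value, 0.001)
})
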