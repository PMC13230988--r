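test_that("OD table round-trips through CSV with times sorted ascending", {
  path <- withr::local_tempfile(fileext = ".csv")
  s1 <- od_series("w1", "0", 1, c(0, 1, 2), c(0.02, 0.033, 0.054))
  s2 <- od_series("w2", "1000", 1, c(0, 1, 2), c(0.021, 0.03, 0.049))
  write_od_table(list(s1, s2), path)
  back <- read_od_table(path)
  expect_length(back, 2)
  m <- match("w1", vapply(back, `[[`, character(1), "sample_id"))
  expect_equal(back[[m]]$times, s1$times)
  expect_equal(back[[m]]$ods, s1$ods)

  # shuffled rows parse into the same sorted series
  df <- utils::read.csv(path)
  utils::write.csv(df[rev(seq_len(nrow(df))), ], path, row.names = FALSE)
  back2 <- read_od_table(path)
  m2 <- match("w1", vapply(back2, `[[`, character(1), "sample_id"))
  expect_equal(back2[[m2]]$times, s1$times)
  expect_equal(back2[[m2]]$ods, s1$ods)
})

test_that("reader reports missing columns, bad values, and applies blanks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,condition,replicate,time_h",
               "w1,0,1,0"), path)
  expect_error(read_od_table(path), "od600")

  writeLines(c("sample_id,condition,replicate,time_h,od600",
               "w1,0,1,0,oops"), path)
  expect_error(read_od_table(path), "row 1")

  # blank subtraction: mean of blank wells removed, blanks dropped
  writeLines(c("sample_id,condition,replicate,time_h,od600",
               "w1,treat,1,0,0.15", "w1,treat,1,1,0.25",
               "w1,treat,1,2,0.45", "w1,treat,1,3,0.85",
               "b1,blank,1,0,0.05", "b1,blank,1,1,0.05"), path)
  out <- read_od_table(path, od_layout(blank_condition = "blank"))
  expect_length(out, 1)
  expect_equal(out[[1]]$ods, c(0.1, 0.2, 0.4, 0.8))
})

test_that("one-sample one-sided t test matches the direct formula", {
  x <- c(0.9, 0.95, 1.0, 1.05)
  res <- one_sample_t_one_sided(x, 1, "less")
  t_manual <- (mean(x) - 1) / (sd(x) / sqrt(4))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$statistic, -0.7745967, tolerance = 1e-6)
  expect_equal(res$dof, 3)
  expect_equal(res$p_value, pt(t_manual, 3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.2474, tolerance = 1e-3)

  # symmetry: all values at mu0 give the indifferent one-sided p
  expect_equal(one_sample_t_one_sided(c(1, 1, 1), 1, "less")$p_value, 0.5)
  # complementarity of the two one-sided alternatives
  pl <- one_sample_t_one_sided(x, 1, "less")$p_value
  pg <- one_sample_t_one_sided(x, 1, "greater")$p_value
  expect_equal(pl + pg, 1, tolerance = 1e-12)

  expect_error(one_sample_t_one_sided(1, 1, "less"), "degenerate")
  expect_error(one_sample_t_one_sided(c(2, 2, 2), 1, "less"), "degenerate")
})

test_that("Welch test matches the unequal-variance formula", {
  a <- c(78, 80, 76); b <- c(62, 61, 63)
  res <- welch_t_two_sided(a, b)
  se2 <- var(a) / 3 + var(b) / 3
  t_manual <- (mean(a) - mean(b)) / sqrt(se2)
  dof_manual <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$dof, dof_manual, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  # Welch dof strictly below the pooled-t dof when variances differ
  a2 <- c(1, 1, 1); b2 <- c(0.8, 1.0, 1.3)
  res2 <- welch_t_two_sided(a2, b2)
  expect_true(is.finite(res2$statistic))
  expect_lt(res2$dof, length(a2) + length(b2) - 2)

  expect_equal(welch_t_two_sided(a, a)$p_value,
               stats::t.test(a, a)$p.value)
  expect_equal(welch_t_two_sided(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(welch_t_two_sided(1, b), "degenerate")
})

test_that("BH adjustment equals the brute-force min-over-ranks formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(42, {
    for (i in 1:20) {
      p <- runif(sample(2:30, 1))
      adj <- benjamini_hochberg(p)
      expect_equal(adj, bh_brute_force(p), tolerance = 1e-12)
      # permutation invariance
      perm <- sample(length(p))
      expect_equal(benjamini_hochberg(p[perm]), adj[perm],
                   tolerance = 1e-12)
      # monotone in rank order, capped at 1
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
      expect_true(all(adj <= 1))
    }
  })
})

test_that("adjust_family attaches BH-adjusted p-values not below the raw", {
  tests <- list(one_sample_t_one_sided(c(0.7, 0.75, 0.8), 1, "less"),
                one_sample_t_one_sided(c(0.99, 1.01, 0.98), 1, "less"),
                one_sample_t_one_sided(c(0.9, 0.92, 0.95), 1, "less"))
  fam <- adjust_family(tests)
  raw <- vapply(fam, `[[`, numeric(1), "p_value")
  adj <- vapply(fam, `[[`, numeric(1), "adjusted_p")
  expect_true(all(adj >= raw - 1e-12))
  expect_equal(adj, benjamini_hochberg(raw))
})
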