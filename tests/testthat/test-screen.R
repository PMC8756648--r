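test_that("relative improvement is the fractional gain over the control mean", {
  expect_equal(relative_improvement(1200, 1000), 0.20)
  expect_equal(relative_improvement(1000, 1000), 0.0)
  expect_equal(relative_improvement(c(1100, 1200, 1300),
                                    c(1000, 1000, 1000)), 0.20)
  expect_error(relative_improvement(1200, 0), "control mean")
  expect_error(relative_improvement(1200, c(-10, 10)), "control mean")
})

test_that("per-plate and global control normalisation both work", {
  plate <- data.frame(
    plate_id = rep(c("p1", "p2"), each = 3),
    well = c("A1", "A2", "A3", "A1", "A2", "A3"),
    clone_id = c("control", "c1", "c2", "control", "c1", "c3"),
    fluorescence = c(1000, 1200, 900, 2000, 2400, 2000),
    is_control = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  per <- screen_improvements(plate)
  expect_equal(per$improvement[per$clone_id == "c1" & per$plate_id == "p1"], 0.2)
  expect_equal(per$improvement[per$clone_id == "c1" & per$plate_id == "p2"], 0.2)
  expect_equal(per$improvement[per$clone_id == "c3"], 0.0)

  glob <- screen_improvements(plate, control = "global")
  expect_equal(glob$improvement[glob$clone_id == "c1" & glob$plate_id == "p2"],
               2400 / 1500 - 1)

  bad <- plate; bad$is_control[4] <- FALSE
  expect_error(screen_improvements(bad), "no control wells.*p2")
})

test_that("shortlisting is inclusive at the threshold and monotone in it", {
  res <- data.frame(clone_id = c("a", "b", "c"),
                    improvement = c(0.19, 0.20, 0.21))
  expect_equal(nrow(suppressMessages(shortlist(res, 0.20))), 2)
  expect_equal(nrow(suppressMessages(shortlist(res, 0))), 3)

  set.seed(31)
  imp <- data.frame(clone_id = sprintf("c%03d", 1:100),
                    improvement = rnorm(100, 0.1, 0.3))
  sizes <- vapply(seq(0, 1, by = 0.05), function(th) {
    nrow(suppressMessages(shortlist(imp, th)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("rescaling a whole plate leaves improvements unchanged", {
  pl <- gen_plate(20, noise_cv = 0.05, seed = 5)
  scaled <- pl
  scaled$fluorescence <- scaled$fluorescence * 7.3
  expect_equal(screen_improvements(scaled)$improvement,
               screen_improvements(pl)$improvement, tolerance = 1e-12)
})

test_that("shortlisted clones collapse to unique signal peptides with counts", {
  clones <- data.frame(clone_id = c("k1", "k2", "k3", "k4", "k5"),
                       sp_seq = c("MKA", "MKA", "MKB", "MKC", "MKC"))
  dd <- dedupe_to_signal_peptides(clones)
  expect_equal(nrow(dd), 3)
  expect_equal(dd$n_clones, c(2, 2, 1))
  expect_identical(dd$sp_seq, c("MKA", "MKC", "MKB"))  # count desc, then seq
  expect_identical(dd$clone_ids[1], "k1,k2")

  all_same <- data.frame(clone_id = c("k1", "k2"), sp_seq = "MKA")
  expect_equal(nrow(dedupe_to_signal_peptides(all_same)), 1)
  all_diff <- data.frame(clone_id = c("k1", "k2"), sp_seq = c("MKA", "MKB"))
  expect_equal(dedupe_to_signal_peptides(all_diff)$n_clones, c(1, 1))

  miss <- data.frame(clone_id = c("k1", "k2"), sp_seq = c("MKA", NA))
  expect_warning(dd2 <- dedupe_to_signal_peptides(miss), "k2")
  expect_equal(nrow(dd2), 1)
})

test_that("oversampling folds match the published screening scales", {
  lp <- oversampling_fold(1630, 155)
  expect_equal(lp$fold, 10.5, tolerance = 0.005)
  expect_true(lp$fold > 10)
  pa <- oversampling_fold(1179, 110)
  expect_equal(pa$fold, 10.7, tolerance = 0.005)
  expect_true(pa$fold > 10)
  even <- oversampling_fold(100, 100)
  expect_equal(even$fold, 1.0)
  expect_false(even$meets_target)
  expect_error(oversampling_fold(100, 0), "library_size")
})

test_that("triplicate confirmation combines effect direction and significance", {
  expect_warning(res <- confirm_round2(c(118, 118, 118), c(100, 100, 100)),
                 "unequal means")
  expect_equal(res$percent_increase, 18)
  expect_equal(res$p_value, 0)
  expect_true(res$confirmed)

  expect_warning(null <- confirm_round2(c(100, 100, 100), c(100, 100, 100)),
                 "equal means")
  expect_equal(null$percent_increase, 0)
  expect_false(null$confirmed)

  # planted +30% effect at 5% replicate noise is confirmed
  set.seed(17)
  ctrl <- 1000 * (1 + rnorm(3, 0, 0.05))
  cand <- 1300 * (1 + rnorm(3, 0, 0.05))
  res2 <- confirm_round2(cand, ctrl)
  expect_true(res2$confirmed)
  expect_equal(res2$percent_increase, 30, tolerance = 0.2)

  expect_error(confirm_round2(c(1, 2), c(1, 2, 3)), ">= 3 replicates")
})

test_that("planted effects well above threshold are always recovered, nulls never", {
  # 200 seeded simulations: 3-replicate clones, 5% CV, effects at twice
  # the 20% shortlist threshold
  for (seed in 1:200) {
    pl <- gen_plate(10, noise_cv = 0.05, replicates = 3,
                    effects = c(rep(0.4, 2), rep(0, 8)), seed = seed)
    hits <- suppressMessages(shortlist(screen_improvements(pl), 0.2))$clone_id
    expect_setequal(hits, c("clone_0001", "clone_0002"))
  }
})

test_that("plate tables round-trip through TSV with validation", {
  pl <- gen_plate(5, noise_cv = 0, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_screen_tsv(pl, path)
  back <- read_plate_tsv(path)
  expect_equal(back$fluorescence, pl$fluorescence)
  expect_equal(back$is_control, pl$is_control)
})
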