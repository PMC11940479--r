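test_that("plating efficiency and survival fraction follow the definitions", {
  expect_equal(plating_efficiency(100, 100), 100)
  expect_equal(plating_efficiency(0, 500), 0)
  expect_equal(plating_efficiency(30, 200), 15)
  expect_error(plating_efficiency(10, 0), "positive")
  expect_equal(survival_fraction(20, 400, 50), 0.1)
  # untreated well whose yield equals the control PE has SF = 1
  expect_equal(survival_fraction(45, 90, 50), 1)
  expect_error(survival_fraction(20, 400, 0), "control_pe")
  # joint scale invariance in (colonies, seeded)
  expect_equal(survival_fraction(20, 400, 37), survival_fraction(40, 800, 37))
  expect_equal(plating_efficiency(13, 170), plating_efficiency(26, 340))
})

test_that("replicate reduction matches a spreadsheet-style oracle", {
  rec <- toy_records()
  g <- default_geom()
  dom <- tiny_domain()
  params <- tibble::tibble(cell_line = "L1", alpha = 0.3, beta = 0.02)
  pts <- reduce_cfa(rec, params, g, dom)
  # hand computation: PE is 50% in bio 1 and 40% in bio 2
  # bio 1, 1 Gy: colonies 120,100 of 400 -> SF 0.6, 0.5
  # bio 2, 1 Gy: colonies 90,70 of 400 at PE 40 -> SF 0.5625, 0.4375
  expect_equal(
    dplyr::filter(pts, dose_level_gy == 1)$sf,
    c(0.6, 0.5, 0.5625, 0.4375)
  )
  s <- summarize_replicates(rec, params, g, dom)
  row1 <- dplyr::filter(s, dose_level_gy == 1)
  expect_equal(row1$sf_mean, mean(c(0.6, 0.5, 0.5625, 0.4375)))
  expect_equal(row1$sf_sem, sd(c(0.6, 0.5, 0.5625, 0.4375)) / 2)
  expect_equal(row1$n, 4L)
  # EUD is the 4-fraction BB equivalent of the dose level
  p <- lq_params(0.3, 0.02)
  expect_equal(row1$eud_gy,
               eud_single_fraction(p, sf_uniform(p, rep(1, 4))),
               tolerance = 1e-9)
})

test_that("reduction is invariant to record order and to replicate scaling", {
  rec <- toy_records()
  params <- tibble::tibble(cell_line = "L1", alpha = 0.3, beta = 0.02)
  g <- default_geom(); dom <- tiny_domain()
  base <- summarize_replicates(rec, params, g, dom)
  shuffled <- summarize_replicates(rec[sample(nrow(rec)), ], params, g, dom)
  expect_equal(shuffled, base)
  # identical wells give zero SEM
  rep18 <- tibble::tibble(
    cell_line = "L1", modality = c("control", rep("BB", 18)),
    dose_level_gy = c(0, rep(2, 18)), bio_rep = 1,
    tech_rep = seq_len(19), cells_seeded = 100,
    colonies = c(50, rep(20, 18))
  )
  s18 <- summarize_replicates(rep18, params, g, dom)
  expect_equal(s18$sf_sem, 0)
  expect_equal(s18$n, 18L)
  expect_equal(s18$sf_mean, 0.4)
})

test_that("a missing 0 Gy control is reported with its replicate", {
  rec <- dplyr::filter(toy_records(), !(dose_level_gy == 0 & bio_rep == 2))
  params <- tibble::tibble(cell_line = "L1", alpha = 0.3, beta = 0.02)
  expect_error(reduce_cfa(rec, params, default_geom(), tiny_domain()),
               "bio_rep 2")
})

test_that("CFA CSV round-trips and schema violations name rows", {
  rec <- toy_records()
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_cfa(rec, path)
  back <- read_cfa(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  bad <- rec
  bad$cells_seeded[3] <- 0
  expect_error(write_cfa(bad, path), "row\\(s\\): 3")
  expect_error(validate_cfa <- read_cfa(path) |> dplyr::select(-colonies) |> mrtfrac:::validate_cfa(),
               "missing column")
})

test_that("LQ fitting recovers exact data and solves the two-point system", {
  doses <- c(1, 2, 4, 6, 8)
  truth <- c(alpha = 0.29075, beta = 0.01928)
  d <- tibble::tibble(dose_gy = doses,
                      sf = exp(-(truth[1] * doses + truth[2] * doses^2)))
  f <- fit_lq(d)
  expect_equal(f$params$alpha, unname(truth[1]), tolerance = 1e-10)
  expect_equal(f$params$beta, unname(truth[2]), tolerance = 1e-10)
  expect_equal(glance(f)$rmse_log, 0, tolerance = 1e-12)
  # two exact points: parameters solve the 2x2 linear system
  d2 <- tibble::tibble(dose_gy = c(2, 5), sf = c(0.5, 0.05))
  f2 <- fit_lq(d2)
  sol <- solve(matrix(c(2, 5, 4, 25), 2, 2), -log(c(0.5, 0.05)))
  expect_equal(f2$params$alpha, sol[1], tolerance = 1e-10)
  expect_equal(f2$params$beta, sol[2], tolerance = 1e-10)
  expect_named(tidy(f2), c("term", "estimate", "std.error"))
  expect_error(fit_lq(tibble::tibble(dose_gy = c(2, 2), sf = c(0.5, 0.4))),
               "distinct")
  expect_error(fit_lq(tibble::tibble(dose_gy = c(1, 2), sf = c(0.5, 0))),
               "> 0")
})

test_that("beta is clamped at zero for linear-survival data and alpha stays accurate", {
  # beta truth 0 with multiplicative (log-scale) noise: the unconstrained
  # beta estimate falls below zero about half the time and is projected to
  # the boundary; the unconstrained alpha estimate is unbiased, and the
  # projected alpha is at least as precise (the projection shrinks variance
  # at the cost of a small conditional bias)
  set.seed(77)
  doses <- rep(c(1, 2, 4, 6, 8), each = 6)
  alpha0 <- 0.56606
  fits <- replicate(500, {
    d <- tibble::tibble(dose_gy = doses,
                        sf = exp(-alpha0 * doses + rnorm(length(doses), 0, 0.1)))
    f <- fit_lq(d)
    c(alpha = f$params$alpha, beta = f$params$beta,
      alpha_u = f$unconstrained[["alpha"]],
      clamped = as.numeric(f$clamped == "beta"))
  })
  expect_true(all(fits["beta", ] >= 0))
  expect_gt(mean(fits["clamped", ]), 0.25)
  expect_lt(abs(mean(fits["alpha_u", ]) - alpha0),
            3 * sd(fits["alpha_u", ]) / sqrt(ncol(fits)))
  expect_lte(sqrt(mean((fits["alpha", ] - alpha0)^2)),
             sqrt(mean((fits["alpha_u", ] - alpha0)^2)))
})
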