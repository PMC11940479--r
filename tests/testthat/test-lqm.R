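test_that("uniform LQ survival follows the closed form", {
  p <- a549()
  expect_equal(sf_uniform(p, c(0, 0, 0)), 1)
  expect_equal(sf_uniform(lq_params(log(2), 0), 1), 0.5)
  # hand evaluation: exp(-(0.29075*2 + 0.01928*4))
  expect_equal(sf_uniform(p, 2), exp(-(0.29075 * 2 + 0.01928 * 4)))
  expect_equal(sf_uniform(p, 2), 0.5175651, tolerance = 1e-6)
  # per-fraction accumulation = product of single fractions
  expect_equal(sf_uniform(p, c(1.5, 2, 3)),
               sf_uniform(p, 1.5) * sf_uniform(p, 2) * sf_uniform(p, 3))
  expect_error(sf_uniform(p, c(1, -1)), "negative")
  expect_error(lq_params(0, 0), "both")
})

test_that("spatial survival reduces to the uniform limit", {
  p <- a549()
  dom <- tiny_domain()
  g <- default_geom()
  # all broad-beam fractions: exact agreement
  bb <- study_plan("BB", 1.7, g)
  expect_equal(sf_spatial(p, bb, dom), sf_uniform(p, rep(1.7, 4)),
               tolerance = 1e-15)
  # microbeam with PVDR 1 is uniform at the peak dose
  gu <- microbeam_geometry(pvdr = 1)
  mu <- study_plan("MRT", 2.2, gu)
  expect_equal(sf_spatial(p, mu, dom), sf_uniform(p, rep(2.2, 4)),
               tolerance = 1e-12)
})

test_that("two-level field survival matches the piecewise closed form", {
  # half the area at the peak dose, half at the valley dose, single fraction
  p <- a549()
  g <- half_geom(pvdr = 10)
  dom <- tiny_domain(extent_mm = 1.2, resolution_um = 5)
  plan <- fraction_plan(g, tibble::tibble(modality = "microbeam",
                                          peak_dose_gy = 6, angle_deg = 0))
  expected <- 0.5 * (sf_uniform(p, 6) + sf_uniform(p, 0.6))
  expect_equal(sf_spatial(p, plan, dom), expected, tolerance = 1e-12)
})

test_that("EUD inversion is exact, stable and monotone", {
  p <- a549()
  expect_equal(eud_single_fraction(p, 1), 0)
  # near-zero beta: continuous linear limit
  expect_equal(eud_single_fraction(lq_params(0.56606, 0), 0.1),
               log(10) / 0.56606, tolerance = 1e-12)
  # round trip through sf_uniform
  for (d in c(0.3, 1, 4.7, 12)) {
    expect_equal(eud_single_fraction(p, sf_uniform(p, d)), d, tolerance = 1e-9)
  }
  # strictly increasing as survival decreases
  sfs <- c(0.9, 0.5, 0.1, 0.01)
  euds <- eud_single_fraction(p, sfs)
  expect_true(all(diff(euds) > 0))
  expect_error(eud_single_fraction(p, 0), "\\(0, 1\\]")
  expect_error(eud_single_fraction(p, 1.2), "\\(0, 1\\]")
})

test_that("quadratic-formula EUD agrees with brute-force bisection", {
  set.seed(42)
  bisect_eud <- function(alpha, beta, sf) {
    L <- -log(sf)
    lo <- 0; hi <- 1
    while (alpha * hi + beta * hi^2 < L) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (alpha * mid + beta * mid^2 < L) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (i in 1:50) {
    alpha <- runif(1, 0.01, 2); beta <- runif(1, 0, 0.1)
    sf <- exp(runif(1, log(1e-6), log(0.999)))
    expect_equal(eud_single_fraction(lq_params(alpha, beta), sf),
                 bisect_eud(alpha, beta, sf), tolerance = 1e-9)
  }
})

test_that("rotated fractions kill more than overlapping fractions", {
  p <- a549()  # beta > 0
  g <- default_geom()
  dom <- tiny_domain()
  ov <- sf_spatial(p, study_plan("MRT", 8, g), dom)
  rot <- sf_spatial(p, study_plan("MRT+R", 8, g), dom)
  expect_lt(rot, ov)
  e_ov <- eud_of_plan(p, study_plan("MRT", 8, g), dom)$eud_single_fraction_gy
  e_rot <- eud_of_plan(p, study_plan("MRT+R", 8, g), dom)$eud_single_fraction_gy
  expect_gt(e_rot, e_ov)
})

test_that("eud_of_plan matches closed forms for uniform plans", {
  p <- a549()
  g <- default_geom()
  dom <- tiny_domain()
  # a single uniform fraction is its own EUD
  one <- fraction_plan(g, tibble::tibble(modality = "broad_beam",
                                         peak_dose_gy = 3.3, angle_deg = 0))
  expect_equal(eud_of_plan(p, one, dom)$eud_single_fraction_gy, 3.3,
               tolerance = 1e-9)
  # 4 x d: E solves alpha E + beta E^2 = 4 (alpha d + beta d^2), E < 4d
  d <- 2
  L <- 4 * (p$alpha * d + p$beta * d^2)
  E_closed <- (-p$alpha + sqrt(p$alpha^2 + 4 * p$beta * L)) / (2 * p$beta)
  e <- eud_of_plan(p, study_plan("BB", d, g), dom)$eud_single_fraction_gy
  expect_equal(e, E_closed, tolerance = 1e-9)
  expect_lt(e, 4 * d)
})

test_that("eud_sweep equals per-plan evaluation and is monotone in peak dose", {
  p <- a549()
  g <- default_geom()
  dom <- tiny_domain()
  sweep <- eud_sweep(p, g, c(0, 45, 90, 135), c(2, 5, 9), dom)
  for (i in seq_len(nrow(sweep))) {
    direct <- eud_of_plan(p, study_plan("MRT+R", sweep$peak_dose_gy[i], g), dom)
    expect_equal(sweep$sf[i], direct$sf, tolerance = 1e-12)
  }
  expect_true(all(diff(sweep$eud_single_fraction_gy) > 0))
})

test_that("inverse planning hits the survival target and matches an oracle", {
  p <- a549()
  g <- default_geom()
  dom <- tiny_domain()
  # degenerate uniform case returns the uniform dose
  gu <- microbeam_geometry(pvdr = 1)
  target <- sf_uniform(p, rep(1.8, 4))
  expect_equal(
    peak_dose_for_target_sf(p, gu, rep(0, 4), target, dom),
    1.8, tolerance = 1e-4
  )
  # independent fixed-step bisection oracle at 10x tighter dose tolerance
  angles <- c(0, 45, 90, 135)
  pk <- peak_dose_for_target_sf(p, g, angles, 0.2, dom)
  oracle <- local({
    lo <- 0; hi <- 200
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      s <- sf_spatial(p, fraction_plan(g, tibble::tibble(
        modality = "microbeam", peak_dose_gy = mid, angle_deg = angles)), dom)
      if (s > 0.2) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
  expect_equal(pk, oracle, tolerance = 1e-4)
  expect_equal(sf_spatial(p, study_plan("MRT+R", pk, g), dom), 0.2,
               tolerance = 1e-6)
  # rotated plans need a lower peak dose than overlapping plans
  pk_ov <- peak_dose_for_target_sf(p, g, rep(0, 4), 0.2, dom)
  expect_lt(pk, pk_ov)
  expect_error(peak_dose_for_target_sf(p, g, angles, 1, dom), "target_sf")
})

test_that("heterogeneous fields spare cells relative to their mean field", {
  # survival-curve convexity regime (alpha^2 >= 2 beta), as for both cell lines
  set.seed(11)
  g_pool <- list(default_geom(), half_geom(5), microbeam_geometry(40, 200, 20))
  dom <- tiny_domain(extent_mm = 0.8)
  for (i in 1:25) {
    p <- rand_convex_lq()
    g <- g_pool[[sample(3, 1)]]
    n_fx <- sample(1:4, 1)
    peaks <- runif(n_fx, 0.5, 15)
    angles <- runif(n_fx, 0, 180)
    plan <- fraction_plan(g, tibble::tibble(
      modality = "microbeam", peak_dose_gy = peaks, angle_deg = angles))
    mean_doses <- vapply(seq_len(n_fx), function(k) {
      mean(fraction_dose_map(g, peaks[k], angles[k], dom)$values)
    }, numeric(1))
    expect_gte(sf_spatial(p, plan, dom), sf_uniform(p, mean_doses))
  }
})

test_that("spatial survival stays in (0, 1] and equals 1 only at zero dose", {
  p <- mrc5()
  g <- default_geom()
  dom <- tiny_domain()
  zero <- study_plan("MRT", 0, g)
  expect_equal(sf_spatial(p, zero, dom), 1)
  s <- sf_spatial(p, study_plan("MRT", 30, g), dom)
  expect_gt(s, 0)
  expect_lt(s, 1)
})
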