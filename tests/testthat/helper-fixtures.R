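# Shared fixtures: small domains keep the spatial integrals fast; the
# default full-scale domain is exercised in the acceptance tests.

tiny_domain <- function(extent_mm = 1.2, resolution_um = 5) {
  integration_domain(extent_mm = extent_mm, resolution_um = resolution_um)
}

default_geom <- function(...) microbeam_geometry(...)

a549 <- function() lq_params(0.29075, 0.01928)
mrc5 <- function() lq_params(0.56606, 0.00004)

# geometry whose stripe pattern is exactly half peak / half valley and whose
# 5 um grid samples both regions exactly (slit 30, pitch 60): closed-form
# survival of the two-level field is then exact
half_geom <- function(pvdr = 10) {
  microbeam_geometry(slit_width_um = 30, pitch_um = 60, pvdr = pvdr)
}

# random LQ parameters inside the survival-convexity regime (alpha^2 >= 2 beta),
# the regime of both study cell lines, where heterogeneous fields spare cells
rand_convex_lq <- function() {
  alpha <- runif(1, 0.15, 0.9)
  beta <- runif(1, 0, 0.9 * alpha^2 / 2)
  lq_params(alpha, beta)
}

# small complete CFA record set built by hand (values chosen round);
# one cell line, one arm, two bio reps
toy_records <- function() {
  tibble::tibble(
    cell_line = "L1",
    modality = c(rep("control", 4), rep("BB", 8)),
    dose_level_gy = c(rep(0, 4), rep(c(1, 2), each = 4)),
    bio_rep = rep(c(1, 1, 2, 2), 3),
    tech_rep = rep(c(1, 2), 6),
    cells_seeded = c(100, 100, 200, 200, rep(400, 8)),
    colonies = c(50, 50, 80, 80, 120, 100, 90, 70, 60, 50, 45, 35)
  )
}
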