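# Poincare-ball primitives against closed-form and trigonometric oracles.

test_that("distance matches closed forms and contracts", {
  # radial point: d(0, r e1) = 2 artanh(r); also arccosh(1 + 2r^2/(1-r^2))
  expect_equal(poincare_distance(c(0, 0), c(0.5, 0)), 2 * atanh(0.5),
               tolerance = 1e-12)
  expect_equal(poincare_distance(c(0, 0), c(0.5, 0)), acosh(5 / 3),
               tolerance = 1e-12)
  # identity and symmetry
  set.seed(11)
  for (i in 1:20) {
    u <- runif(4, -0.6, 0.6); v <- runif(4, -0.6, 0.6)
    expect_identical(poincare_distance(u, u), 0)
    expect_equal(poincare_distance(u, v), poincare_distance(v, u))
    expect_gt(poincare_distance(u, v), 0)
  }
  expect_error(poincare_distance(c(1, 0), c(0, 0)), "unit ball")
  expect_equal(origin_distance(c(0.3, 0, 0)), 2 * atanh(0.3), tolerance = 1e-12)
})

test_that("distance agrees with the Mobius gyrovector form", {
  set.seed(21)
  for (i in 1:200) {
    u <- runif(5, -1, 1); u <- u * runif(1, 0, 0.95) / sqrt(sum(u^2))
    v <- runif(5, -1, 1); v <- v * runif(1, 0, 0.95) / sqrt(sum(v^2))
    expect_equal(poincare_distance(u, v), gyro_distance(u, v),
                 tolerance = 1e-11)
  }
})

test_that("distance and apex angle are rotation invariant", {
  set.seed(31)
  R <- random_rotation(6)
  for (i in 1:25) {
    u <- runif(6, -0.4, 0.4); v <- runif(6, -0.4, 0.4)
    expect_equal(poincare_distance(drop(R %*% u), drop(R %*% v)),
                 poincare_distance(u, v), tolerance = 1e-10)
    expect_equal(angle_at_apex(drop(R %*% u), drop(R %*% v)),
                 angle_at_apex(u, v), tolerance = 1e-10)
  }
})

test_that("projection into the ball preserves direction and caps the norm", {
  expect_identical(project_to_ball(c(0, 0, 0)), c(0, 0, 0))
  x <- c(0.3, 0, 0)
  expect_identical(project_to_ball(x), x)
  y <- project_to_ball(c(2, 0, 0), eps_ball = 1e-5)
  expect_equal(sqrt(sum(y^2)), 1 - 1e-5, tolerance = 1e-15)
  expect_equal(y / sqrt(sum(y^2)), c(1, 0, 0))
  # matrix form, rowwise
  m <- project_to_ball(rbind(c(3, 4), c(0.1, 0.1)))
  expect_equal(sqrt(sum(m[1, ]^2)), 1 - 1e-5)
  expect_equal(m[2, ], c(0.1, 0.1))
})

test_that("Riemannian rescaling applies the inverse metric factor", {
  g <- c(1, -2, 3)
  expect_equal(riemannian_rescale(c(0, 0, 0), g), g / 4)
  x <- c(0.6, 0, 0)
  expect_equal(riemannian_rescale(x, g), g * (1 - 0.36)^2 / 4)
  expect_equal(riemannian_rescale(x, c(0, 0, 0)), c(0, 0, 0))
  expect_error(riemannian_rescale(c(1.2, 0, 0), g), "unit ball")
})

test_that("cone aperture matches scalar evaluation and its domain", {
  expect_equal(cone_aperture(c(0.5, 0), 0.1), asin(0.1 * 0.75 / 0.5),
               tolerance = 1e-12)
  expect_equal(cone_aperture(c(0.2, 0), 0.1), asin(0.1 * 0.96 / 0.2),
               tolerance = 1e-12)
  expect_true(is.na(cone_aperture(c(0.05, 0), 0.1)))
  # r_min: closed form vs bisection oracle; aperture there is pi/2
  rm <- cone_r_min(0.1)
  expect_equal(rm, r_min_bisect(0.1), tolerance = 1e-9)
  expect_equal(cone_aperture(c(rm, 0), 0.1), pi / 2, tolerance = 1e-6)
  # strictly decreasing in the norm on a grid
  rr <- seq(rm, 0.999, length.out = 80)
  psis <- cone_aperture(cbind(rr, 0), 0.1)
  expect_true(all(diff(psis) < 0))
})

test_that("apex angle matches planar trigonometry", {
  expect_equal(angle_at_apex(c(0.5, 0), c(0.7, 0)), 0)
  expect_equal(angle_at_apex(c(0.5, 0), c(0.3, 0)), pi)
  expect_equal(angle_at_apex(c(0.5, 0), c(0.5, 0.2)), pi / 2,
               tolerance = 1e-12)
  expect_error(angle_at_apex(c(0, 0), c(0.5, 0)), "origin")
  expect_error(angle_at_apex(c(0.5, 0), c(0.5, 0)), "differ")
})

test_that("cone membership and hinge energy follow the aperture", {
  apex <- c(0.5, 0)
  expect_true(in_cone(apex, c(0.6, 0), 0.1))
  expect_false(in_cone(apex, c(0, 1e-3), 0.1))     # near-origin member
  # member at apex angle 0.2 rad: outside since psi ~ 0.1506
  psi <- cone_aperture(apex, 0.1)
  y <- c(0.5 + 0.1 * cos(0.2), 0.1 * sin(0.2))
  expect_false(in_cone(apex, y, 0.1))
  expect_equal(cone_energy(apex, y, 0.1), 0.2 - psi, tolerance = 1e-12)
  # inside the cone: zero energy
  y2 <- c(0.5 + 0.1 * cos(0.05), 0.1 * sin(0.05))
  expect_identical(cone_energy(apex, y2, 0.1), 0)
  # gated apex: zero energy by decision, membership errors
  expect_identical(cone_energy(c(0.01, 0), c(0.5, 0), 0.1), 0)
  expect_error(in_cone(c(0.01, 0), c(0.5, 0), 0.1), "undefined")
  # worked value: angle pi/2 at eligible apex
  y3 <- c(0.5, 0.3)
  expect_equal(angle_at_apex(apex, y3), pi / 2, tolerance = 1e-12)
  expect_equal(cone_energy(apex, y3, 0.1), pi / 2 - asin(0.15),
               tolerance = 1e-12)
})

test_that("nested cones are transitive", {
  set.seed(41)
  K <- 0.1
  viol <- 0
  for (i in 1:300) {
    x <- rnorm(5); x <- x / sqrt(sum(x^2)) * runif(1, cone_r_min(K), 0.6)
    y <- sample_in_cone(x, K, runif(1, sqrt(sum(x^2)) + 0.05, 0.8))
    if (is.na(cone_aperture(y, K))) next
    z <- sample_in_cone(y, K, runif(1, sqrt(sum(y^2)) + 0.02, 0.95))
    stopifnot(in_cone(x, y, K), in_cone(y, z, K))
    if (angle_at_apex(x, z) > cone_aperture(x, K) + 1e-6) viol <- viol + 1
  }
  expect_identical(viol, 0)
})
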