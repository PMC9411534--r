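# The compartment reaction model and its renderer.

two_node_graph <- function(k) {
  compartment_graph(
    nodes = tibble::tibble(id = c("n1", "n2"), volume = c(1000, 500),
                           nuclei = 1L, green = 1),
    edges = tibble::tibble(from = "n1", to = "n2", rate = k)
  )
}

test_that("an isolated bleached compartment decays exponentially", {
  g <- compartment_graph(
    nodes = tibble::tibble(id = "a", volume = 1, nuclei = 0L, green = 1))
  p <- photo_protocol(0, 101, 0, 1, "bleach", "a", 0.1, "green")
  s <- integrate_dynamics(g, p, solver_dt = 0.05)
  expect_equal(as.numeric(s$values[1, 1, ]), exp(-0.1 * s$times),
               tolerance = 1e-9)
})

test_that("integrator matches the matrix-exponential oracle on a k x beta grid", {
  skip_if_not_installed("Matrix")
  for (k in c(0, 0.01, 0.1, 1)) {
    for (beta in c(0, 0.01, 0.1, 1)) {
      g <- two_node_graph(k)
      p <- photo_protocol(0, 31, 0, 10, "bleach", "n1", beta, "green")
      s <- integrate_dynamics(g, p, solver_dt = 0.01)
      oracle <- expm_two_compartment(k, beta, s$times)
      expect_equal(unname(s$values[, 1, ]), unname(oracle),
                   tolerance = 1e-6)
    }
  }
})

test_that("closed-form solution agrees with trivial cases and fine-step numerics", {
  # no exchange: bleached compartment is a plain exponential
  cf <- closed_form_two_compartment(k = 0, beta = 0.1, t = 10)
  expect_equal(cf$c1, exp(-1), tolerance = 1e-12)
  expect_equal(cf$c2, 1, tolerance = 1e-12)
  # no sink: both stay at 1 forever
  cf2 <- closed_form_two_compartment(k = 0.3, beta = 0, t = c(5, 50, 300))
  expect_equal(cf2$c1, rep(1, 3), tolerance = 1e-9)
  expect_equal(cf2$c2, rep(1, 3), tolerance = 1e-9)
  # general case against fine-step integration
  g <- two_node_graph(0.05)
  p <- photo_protocol(0, 21, 0, 1, "bleach", "n1", 0.1, "green")
  s <- integrate_dynamics(g, p, solver_dt = 1e-3)
  cf3 <- closed_form_two_compartment(0.05, 0.1, 20)
  expect_equal(s$values["n1", 1, 21], cf3$c1, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(s$values["n2", 1, 21], cf3$c2, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(closed_form_two_compartment(-1, 0.1, 1), "must be")
})

test_that("volume-weighted mass is conserved without bleach or decay", {
  # equal volumes: the regime in which the symmetric exchange flux
  # conserves total amount
  g <- compartment_graph(
    nodes = tibble::tibble(id = c("a", "b", "c"),
                           volume = 400, nuclei = 0L,
                           green = c(1, 0.2, 0)),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                           rate = c(0.2, 0.07))
  )
  p <- photo_protocol(50, 0, 0, 2, "none")
  s <- integrate_dynamics(g, p)
  total <- colSums(s$values[, 1, ] * g$nodes$volume)
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-9)
})

test_that("photoconversion conserves native + converted Kaede per compartment", {
  g <- compartment_graph(
    nodes = tibble::tibble(id = c("a", "b"), volume = 1, nuclei = 0L,
                           kaede_native = 1, kaede_converted = 0),
    edges = tibble::tibble(from = "a", to = "b", rate = 0.05)
  )
  p <- photo_protocol(2, 20, 10, 2, "convert", "a", 0.5)
  s <- integrate_dynamics(g, p)
  total <- s$values[, "kaede_native", ] + s$values[, "kaede_converted", ]
  expect_equal(as.numeric(total), rep(1, length(total)), tolerance = 1e-9)
})

test_that("increasing exchange strictly increases loss in the unbleached node", {
  loss <- vapply(c(0, 0.01, 0.05, 0.2), function(k) {
    g <- two_node_graph(k)
    p <- photo_protocol(0, 51, 0, 2, "bleach", "n1", 0.4, "green")
    s <- integrate_dynamics(g, p)
    1 - s$values["n2", 1, 51] / s$values["n2", 1, 1]
  }, numeric(1))
  expect_true(all(diff(loss) > 0))
})

test_that("protocol and graph validation raises informative errors", {
  g <- two_node_graph(0.1)
  expect_error(photo_protocol(1, 1, 1, 2, "bleach"), "target_node")
  p_bad <- photo_protocol(0, 10, 0, 2, "bleach", "zzz", 0.1, "green")
  expect_error(integrate_dynamics(g, p_bad), "not a node")
  p_sp <- photo_protocol(0, 10, 0, 2, "bleach", "n1", 0.1, "magenta")
  expect_error(integrate_dynamics(g, p_sp), "species")
  expect_error(
    compartment_graph(
      tibble::tibble(id = c("a", "a"), volume = 1, nuclei = 0L, green = 1)),
    "unique")
  expect_error(
    compartment_graph(
      tibble::tibble(id = "a", volume = 1, nuclei = 0L, green = 1),
      tibble::tibble(from = "a", to = "b", rate = 1)),
    "unknown nodes")
})

test_that("noise-free rendering reproduces concentrations pixel for pixel", {
  g <- two_node_graph(0.05)
  p <- photo_protocol(2, 20, 5, 2, "bleach", "n1", 0.4, "green")
  s <- integrate_dynamics(g, p)
  lab <- matrix(0L, 20, 30)
  lab[3:10, 3:12] <- 1L
  lab[3:10, 15:28] <- 2L
  geom <- field_geometry(lab, 0.2, c("n1", "n2"))
  m <- render_movie(s, geom, gain = 1, background = 0, gaussian_sd = 0)
  for (f in c(1, 10, 27)) {
    expect_equal(m$data[f, 1, 5, 5, 1], s$values["n1", 1, f])
    expect_equal(m$data[f, 1, 5, 20, 1], s$values["n2", 1, f])
    expect_equal(m$data[f, 1, 1, 1, 1], 0)
  }
  bad_geom <- field_geometry(matrix(3L, 4, 4), 0.2, c("n1", "n2", "ghost"))
  expect_error(render_movie(s, bad_geom), "absent")
})

test_that("rendered ROI means stay within the expected noise envelope", {
  m <- make_fixture("two_closed", seed = 42)
  tr <- measure_zone_trace(m, roi_rect(11, 70, 11, 70, id = "n1"), "green")
  s <- m$truth$series
  expected <- 10 + 100 * s$values["n1", "green", ]
  n_px <- 60 * 60
  dev <- abs(tr$i_mean - expected)
  expect_gte(mean(dev <= 5 * 2 / sqrt(n_px)), 0.99)
})

test_that("fixtures are deterministic and cover their documented truth", {
  a <- make_fixture("chain3", seed = 7)
  b <- make_fixture("chain3", seed = 7)
  expect_identical(a$data, b$data)
  c <- make_fixture("chain3", seed = 8)
  expect_false(identical(a$data, c$data))
  expect_error(make_fixture("nope"), "arg")
  f6 <- make_fixture("fig6_like", seed = 1)
  expect_setequal(f6$truth$graph$nodes$id,
                  c("GFP", "H_GFP", "L_GFP", "mCherry1", "mCherry2"))
  open <- f6$truth$graph$edges[f6$truth$graph$edges$open, ]
  expect_setequal(paste(open$from, open$to),
                  c("GFP H_GFP", "GFP L_GFP", "L_GFP mCherry2"))
})
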