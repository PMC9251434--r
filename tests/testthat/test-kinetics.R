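test_that("slowdown factor is quadratic in peptide length", {
  expect_equal(slowdown_factor(1), 1)
  expect_equal(slowdown_factor(2), 4)
  expect_equal(slowdown_factor(10), 100)
  expect_error(slowdown_factor(0.5), ">= 1")
  expect_error(slowdown_factor(-2), "positive")
})

test_that("free diffusion time converts units correctly", {
  # 1 nm at 3 um^2/s: x^2/(2D) = 1 / (2 * 3e-3 nm^2/ns)
  expect_equal(free_diffusion_time(1, 3), 1000 / 6, tolerance = 1e-12)
  # quadratic in thickness
  expect_equal(free_diffusion_time(2, 3), 4 * free_diffusion_time(1, 3))
  # D = 0.5 nm^2/ns = 500 um^2/s gives 1 ns for 1 nm
  expect_equal(free_diffusion_time(1, 500), 1, tolerance = 1e-12)
  expect_error(free_diffusion_time(-1, 3), "positive")
  expect_error(free_diffusion_time(1, 0), "positive")
})

test_that("pore transit composes slowdown with free diffusion", {
  tau_free_ns <- free_diffusion_time(1, 3)
  expect_equal(pore_release_time(1, 1, 3), tau_free_ns * 1e-3)
  expect_equal(pore_release_time(2, 1, 3), 4 * tau_free_ns * 1e-3)
  for (L in c(1, 3, 7, 12)) {
    expect_equal(pore_release_time(L, 1.3, 2.1),
                 slowdown_factor(L) * free_diffusion_time(1.3, 2.1) * 1e-3)
  }
})

test_that("translocation comparison computes ratio and orders", {
  tau <- pore_release_time(10, 1, 3)
  cmp <- translocation_comparison(10, 40, tau)
  expect_equal(cmp$product_generation_s, 0.25)
  expect_equal(cmp$orders_of_magnitude, 4)
  expect_equal(translocation_comparison(10, 80, tau)$ratio, cmp$ratio / 2)
  unity <- translocation_comparison(1, 1, 1e6)
  expect_equal(unity$ratio, 1)
  expect_equal(unity$orders_of_magnitude, 0)
})

test_that("the kinetics chain is invariant under consistent unit rescaling", {
  set.seed(31)
  for (i in 1:6) {
    x <- runif(1, 0.5, 3); D <- runif(1, 1, 5); L <- sample(1:20, 1)
    s <- runif(1, 0.1, 10)  # length-unit scale factor
    # scaling thickness by s and diffusivity by s^2 leaves times unchanged
    expect_equal(pore_release_time(L, s * x, s^2 * D),
                 pore_release_time(L, x, D), tolerance = 1e-12)
  }
})

test_that("transit time is monotone in its parameters", {
  expect_true(pore_release_time(11, 1, 3) > pore_release_time(10, 1, 3))
  expect_true(pore_release_time(10, 1.5, 3) > pore_release_time(10, 1, 3))
  expect_true(pore_release_time(10, 1, 4) < pore_release_time(10, 1, 3))
})

test_that("the consolidated report flags possibly attractive pores", {
  rep1 <- release_kinetics(mean_hydropathy = 2.1)
  expect_true(rep1$attraction_warning)
  rep2 <- release_kinetics(mean_hydropathy = -1.2)
  expect_false(rep2$attraction_warning)
  expect_equal(rep1$tau_pore_us, rep1$slowdown * rep1$tau_free_ns * 1e-3)
})
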