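make_linear_dataset <- function(n, basis, coefs, seed, with_gradients = FALSE) {
  m <- potential_model(basis, coefs)
  el <- character(basis$spec$natoms)
  pool <- c("H", "C", "O", "N", "F", "S", "Cl")
  for (i in seq_along(basis$spec$classes))
    el[basis$spec$classes[[i]]] <- pool[(i - 1) %% length(pool) + 1]
  geoms <- withr::with_seed(seed,
    replicate(n, random_generic_geometry(el), simplify = FALSE))
  build_dataset(m, geoms, with_gradients = with_gradients)
}

test_that("seeded splits are deterministic, exhaustive and disjoint", {
  set.seed(411)
  geoms <- replicate(40, perturbed_ethanol(), simplify = FALSE)
  d <- pes_dataset(geoms, stats::rnorm(40))
  s1 <- split_dataset(d, 30, seed = 7)
  s2 <- split_dataset(d, 30, seed = 7)
  s3 <- split_dataset(d, 30, seed = 8)
  expect_equal(length(s1$train$energies), 30)
  expect_equal(length(s1$test$energies), 10)
  expect_identical(s1$train$energies, s2$train$energies)
  expect_false(identical(s1$train$energies, s3$train$energies))
  expect_equal(sort(c(s1$train$energies, s1$test$energies)),
               sort(d$energies))
  expect_error(split_dataset(d, 40), "n_train")
  expect_error(split_dataset(d, 0), "n_train")
})

test_that("energy filtering keeps the window above the minimum", {
  set.seed(412)
  geoms <- replicate(3, perturbed_ethanol(), simplify = FALSE)
  d <- pes_dataset(geoms, c(0, 4000, 12000))
  expect_equal(filter_by_energy(d, 10000)$energies, c(0, 4000))
  expect_equal(filter_by_energy(d, Inf)$energies, d$energies)
  # the minimum itself always survives, however tight the window
  out <- filter_by_energy(pes_dataset(geoms, c(5, 5e4, 9e4)), 1e-3)
  expect_equal(out$energies, 5)
})

test_that("least squares exactly recovers a generating coefficient vector", {
  basis <- build_pip_basis("21", 3)   # water-like, 3 atoms
  set.seed(413)
  ctrue <- stats::rnorm(basis$n_p, sd = 100)
  d <- make_linear_dataset(3 * basis$n_p, basis, ctrue, seed = 21)
  fit <- fit_linear(basis, d)
  expect_lt(sqrt(sum((fit$model$coefficients - ctrue)^2)) /
              sqrt(sum(ctrue^2)), 1e-8)
  expect_lt(fit$train_rmse, 1e-8 * stats::sd(d$energies))

  # gradient rows preserve exact recovery
  dg <- make_linear_dataset(basis$n_p, basis, ctrue, seed = 22,
                            with_gradients = TRUE)
  fitg <- fit_linear(basis, dg, gradient_weight = 1)
  expect_lt(sqrt(sum((fitg$model$coefficients - ctrue)^2)) /
              sqrt(sum(ctrue^2)), 1e-8)
  expect_gt(fitg$n_gradient_rows, 0)
})

test_that("a constant-only basis fits a single record exactly", {
  basis <- build_pip_basis("21", 0)
  g <- geometry(c("H", "H", "O"),
                rbind(c(0, 0, 0), c(0, 0, 1), c(0.8, 0.2, 0)))
  d <- pes_dataset(list(g), 412.5)
  fit <- fit_linear(basis, d)
  expect_equal(fit$model$coefficients, 412.5)
  expect_equal(fit$train_rmse, 0)
})

test_that("the fitted minimizer cannot be improved by nudging a coefficient", {
  basis <- build_pip_basis("21", 2)
  set.seed(414)
  geoms <- replicate(30, random_generic_geometry(c("H", "H", "O")),
                     simplify = FALSE)
  d <- pes_dataset(geoms, stats::rnorm(30, sd = 100))   # noisy target
  fit <- fit_linear(basis, d)
  dm <- deltapes:::design_matrix(basis, morse_transform(), d, 0)
  obj <- function(cf) sum((dm$A %*% cf - dm$b)^2)
  base <- obj(fit$model$coefficients)
  for (j in sample.int(basis$n_p, 5)) for (eps in c(-1e-4, 1e-4)) {
    cf <- fit$model$coefficients
    cf[j] <- cf[j] + eps * max(1, abs(cf[j]))
    expect_gte(obj(cf), base)
  }
})

test_that("enlarging the basis never increases training RMSE", {
  set.seed(415)
  ll <- ethanol_forcefield()
  geoms <- replicate(250, perturbed_ethanol(sd = 0.08), simplify = FALSE)
  d <- build_dataset(ll, geoms, energy_unit = "cm-1")
  rmse <- vapply(0:2, function(o)
    fit_linear(build_pip_basis(ethanol_symmetry(), o), d)$train_rmse,
    numeric(1))
  expect_true(all(diff(rmse) <= 1e-8 * max(rmse)))
})

test_that("fitting the residuals of an identical surface gives a null correction", {
  basis <- build_pip_basis(ethanol_symmetry(), 1)
  ll <- ethanol_forcefield()
  set.seed(416)
  geoms <- replicate(50, perturbed_ethanol(), simplify = FALSE)
  hl <- build_dataset(ll, geoms, energy_unit = "cm-1")
  fit <- fit_delta(ll, basis, hl)
  expect_lt(max(abs(fit$model$coefficients)), 1e-9)
})

test_that("a correction expressible in the basis is recovered exactly", {
  basis <- ethanol_basis2()
  ll <- ethanol_forcefield()
  set.seed(417)
  ctrue <- stats::rnorm(basis$n_p, sd = 30)
  truth <- potential_model(basis, ctrue)
  hl_surface <- compose_delta(ll, truth)
  geoms <- replicate(450, perturbed_ethanol(sd = 0.07), simplify = FALSE)
  hl <- build_dataset(hl_surface, geoms, energy_unit = "cm-1")
  fit <- fit_delta(ll, basis, hl)
  composed <- compose_delta(ll, fit$model)
  for (i in 1:5) {
    g <- perturbed_ethanol()
    expect_lt(abs(pes_energy(composed, g) - pes_energy(hl_surface, g)),
              1e-8 * max(1, abs(pes_energy(hl_surface, g))))
  }
})

test_that("rmse_report reproduces closed-form residual cases", {
  b <- build_pip_basis("21", 0)
  g <- geometry(c("H", "H", "O"),
                rbind(c(0, 0, 0), c(0, 0, 1), c(0.8, 0.2, 0)))
  d <- pes_dataset(list(g, g, g), c(100, 100, 100))
  m <- potential_model(b, 100)
  expect_equal(rmse_report(m, d)$rmse_energy, 0)
  m10 <- potential_model(b, 110)
  rep10 <- rmse_report(m10, d)
  expect_equal(rep10$rmse_energy, 10)
  expect_equal(rep10$residuals, rep(10, 3))
})

test_that("datasets round-trip through the XYZ + sidecar format", {
  set.seed(418)
  geoms <- replicate(4, perturbed_ethanol(), simplify = FALSE)
  d <- pes_dataset(geoms, stats::rnorm(4, sd = 100),
                   gradients = matrix(stats::rnorm(4 * 27), 4, 27),
                   provenance = "io fixture")
  stem <- tempfile("dset")
  on.exit(unlink(paste0(stem, c(".xyz", ".dat"))))
  write_dataset(d, stem)
  back <- read_dataset(stem)
  expect_equal(back$energies, d$energies, tolerance = 1e-12)
  expect_equal(back$gradients, d$gradients, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(back$geometries[[3]]$coords - geoms[[3]]$coords)), 1e-10)
})
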