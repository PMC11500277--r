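test_that("Morse variables follow exp(-r/lambda)", {
  t2b <- morse_transform(2, "bohr")
  r_2bohr <- convert_length(2, "bohr", "angstrom")
  expect_equal(morse_variables(r_2bohr, t2b), exp(-1))
  expect_lt(morse_variables(100, t2b), 1e-30)
  # published C-C equilibrium distance over lambda = 2 Bohr
  expect_equal(morse_variables(1.5204, t2b),
               exp(-1.5204 / (2 * 0.52917721067)))
  expect_error(morse_variables(c(1, -0.1), t2b), "positive")
})

test_that("a constant-coefficient surface is flat and permutation-invariant", {
  b <- ethanol_basis2()
  m <- potential_model(b, c(250, rep(0, b$n_p - 1)))
  set.seed(406)
  for (i in 1:5)
    expect_equal(pes_energy(m, perturbed_ethanol()), 250)
  expect_equal(pes_gradient(m, perturbed_ethanol()), rep(0, 27))
})

test_that("PIP model energies are invariant under rigid motion and the group", {
  b <- ethanol_basis2()
  set.seed(407)
  m <- potential_model(b, stats::rnorm(b$n_p, sd = 50))
  g <- perturbed_ethanol()
  e0 <- pes_energy(m, g)
  for (i in 1:5) {
    moved <- translate_geometry(rotate_geometry(g, random_rotation()),
                                stats::rnorm(3))
    expect_lt(abs(pes_energy(m, moved) - e0), 1e-10 * max(1, abs(e0)))
  }
  grp <- m$basis$group
  for (i in seq_len(grp$order)) {
    gp <- apply_permutation(g, grp$atom_perms[i, ])
    expect_lt(abs(pes_energy(m, gp) - e0), 1e-10 * max(1, abs(e0)))
  }
})

test_that("analytic model gradients match finite differences and sum to zero", {
  b <- ethanol_basis2()
  set.seed(408)
  m <- potential_model(b, stats::rnorm(b$n_p, sd = 50))
  for (i in 1:10) {
    g <- perturbed_ethanol()
    ga <- pes_gradient(m, g)
    gn <- deltapes:::numeric_gradient(m, g)
    expect_lt(max(abs(ga - gn)), 1e-6 * sqrt(sum(ga^2)))
    net <- colSums(matrix(ga, 9, 3, byrow = TRUE))
    expect_lt(max(abs(net)), 1e-9)
  }
})

test_that("delta composition is the exact sum of its components", {
  b <- ethanol_basis2()
  set.seed(409)
  ll <- ethanol_forcefield()
  zero <- potential_model(b, rep(0, b$n_p))
  dm0 <- compose_delta(ll, zero)
  corr <- potential_model(b, stats::rnorm(b$n_p, sd = 20))
  dm <- compose_delta(ll, corr)
  for (i in 1:5) {
    g <- perturbed_ethanol()
    e_ll_cm <- convert_energy(pes_energy(ll, g), "kcal/mol", "cm-1")
    expect_equal(pes_energy(dm0, g), e_ll_cm)
    expect_equal(pes_energy(dm, g) - e_ll_cm, pes_energy(corr, g))
    expect_equal(pes_gradient(dm, g),
                 convert_energy(pes_gradient(ll, g), "kcal/mol", "cm-1") +
                   pes_gradient(corr, g))
  }
  expect_error(compose_delta(diatomic_ff(), corr), "atom count")
})

test_that("the correction basis is a small fraction of the low-level basis", {
  # evaluation cost scales with term count: order-2 vs order-4 ethanol bases
  n_small <- count_orbits_burnside(ethanol_symmetry(), 2)
  n_big <- count_orbits_burnside(ethanol_symmetry(), 4)
  expect_lt(n_small / n_big, 0.02)
})

test_that("potential models round-trip through the plain-text format", {
  b <- build_pip_basis("21", 2)
  set.seed(410)
  m <- potential_model(b, stats::rnorm(b$n_p), energy_unit = "cm-1",
                       note = "round-trip fixture")
  path <- withr::local_tempfile(fileext = ".json")
  write_potential_model(m, path)
  m2 <- read_potential_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$transform$lambda, m$transform$lambda)
  g <- geometry(c("H", "H", "O"),
                rbind(c(0, 0, 0), c(0, 0, 1.2), c(0.9, 0.3, 0.1)))
  expect_equal(pes_energy(m2, g), pes_energy(m, g))
})
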