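test_that("the shell-model cascade is registered, ordered and deterministic", {
  m3 <- make_shell_model("3C")
  expect_length(m3$radii, 3)
  expect_equal(m3$conductivities, c(0.33, 0.01, 0.43)) # brain, skull, skin
  m4 <- make_shell_model("4C")
  expect_true(1.79 %in% m4$conductivities) # CSF layer present
  expect_identical(make_shell_model("4C"), make_shell_model("4C"))
  expect_error(make_shell_model("9Z"), "unknown cascade level")
  expect_error(shell_model(c(90, 80), c(0.3, 0.3)), "increasing")
  expect_error(shell_model(c(80, 90), c(0.3, -1)), "> 0")
})

test_that("multi-shell EEG potentials agree with independent oracles", {
  sigma <- 0.33
  R <- 92
  homog <- shell_model(R, sigma, "homogeneous")
  el <- eeg_sensor_array(24, shells = homog)
  el$reference <- "none" # compare unreferenced potentials
  node <- c(30, 20, 45)
  m <- c(1e-9, 2e-9, -1e-9)
  V_series <- as.numeric(eeg_sphere_leadfield(homog, el, node, n_terms = 120) %*% m)
  V_closed <- oracle_homogeneous_potential(el$positions, node, m, sigma, R)
  V_pair <- oracle_monopole_pair_potential(el$positions, node, m, sigma, R)
  expect_lt(max(abs(V_series - V_closed)) / max(abs(V_closed)), 1e-10)
  expect_lt(max(abs(V_series - V_pair)) / max(abs(V_pair)), 1e-5) # finite-dipole limited

  # equal-conductivity multi-shell collapses to the homogeneous solution
  equal4 <- shell_model(c(80, 85, 90, 92), rep(sigma, 4), "equal")
  el2 <- eeg_sensor_array(40)
  for (node in list(c(20, -25, 40), c(0, 10, 65))) {
    g <- eeg_sphere_leadfield(equal4, el2, node, n_terms = 60)
    Vc <- sapply(1:3, function(i) {
      oracle_homogeneous_potential(el2$positions, node, diag(3)[i, ], sigma, R)
    })
    Vc <- sweep(Vc, 2, colMeans(Vc)) # common average, as the array declares
    expect_lt(max(abs(g - Vc)) / max(abs(Vc)), 1e-6)
  }
})

test_that("EEG gains are common-average referenced and reject exterior sources", {
  shells <- fixture_shells()
  el <- eeg_sensor_array(32, shells = shells)
  g <- eeg_sphere_leadfield(shells, el, c(10, 40, 30))
  expect_lt(max(abs(colSums(g))) / max(abs(g)), 1e-12)
  expect_error(eeg_sphere_leadfield(shells, el, c(0, 0, 81)), "innermost shell")
})

test_that("spherical MEG gains are radially silent and match the surface-integral oracle", {
  meg <- meg_sensor_array(16)
  set.seed(31)
  for (k in 1:20) {
    node <- runif(3, -40, 40) + c(0, 0, 20)
    g <- meg_sphere_leadfield(meg, node)
    rhat <- node / sqrt(sum(node^2))
    expect_lt(sqrt(sum((g %*% rhat)^2)) / sqrt(sum(g^2)), 1e-12)
  }
  node <- c(25, -15, 50)
  g <- meg_sphere_leadfield(meg, node)
  g_or <- oracle_geselowitz_gain(meg, node, 92, 0.33)
  expect_lt(max(abs(g - g_or)) / max(abs(g)), 1e-6)
  expect_error(meg_sphere_leadfield(meg, c(0, 0, 0)), "centre")
})

test_that("reference orientations are orthonormal and recover the radial axis", {
  meg <- meg_sensor_array(64)
  node <- c(20, 30, 45)
  o <- reference_orientations(meg_sphere_leadfield(meg, node))
  expect_equal(sum(o$quasi_radial^2), 1, tolerance = 1e-12)
  expect_equal(sum(o$quasi_tangential^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(o$quasi_radial * o$quasi_tangential)), 1e-10)
  rhat <- node / sqrt(sum(node^2))
  expect_gt(abs(sum(o$quasi_radial * rhat)), 1 - 1e-9) # exactly radial null space
  # agreement with a singular-value-decomposition oracle
  g <- eeg_sphere_leadfield(fixture_shells(), eeg_sensor_array(32), c(15, -20, 40))
  sv <- svd(g)
  o2 <- reference_orientations(g)
  expect_gt(abs(sum(o2$quasi_tangential * sv$v[, 1])), 1 - 1e-9)
  expect_gt(abs(sum(o2$quasi_radial * sv$v[, 3])), 1 - 1e-9)
  expect_error(reference_orientations(matrix(0, 5, 3)), "zero")
})

test_that("source spaces honour the anti-inverse-crime offset band", {
  setup <- fixture_eeg_setup(n_nodes = 80, n_refs = 4)
  sp <- setup$space
  expect_equal(sp$node_count, 80)
  expect_equal(nrow(sp$node_positions), 80)
  expect_true(all(row_norms <- sqrt(rowSums(sp$node_positions^2)) < setup$shells$radii[1]))
  for (j in seq_len(nrow(setup$refs))) {
    d <- sqrt(colSums((t(sp$node_positions) - setup$refs[j, ])^2))
    expect_gt(min(d), 0.5)
    expect_lt(min(d), 0.6)
  }
  # determinism
  sp2 <- build_source_space(80, setup$shells, setup$refs, seed = 8)
  expect_identical(sp$node_positions, sp2$node_positions)
  # infeasible density: one node cannot be nearest to two reference sources
  refs_dense <- rbind(c(0, 0, 60), c(0, 0.2, 60), c(0.2, 0, 60))
  expect_error(build_source_space(4, setup$shells, refs_dense, seed = 1),
               "density|infeasible")
})

test_that("leadfield perturbation hits the requested relative magnitude deterministically", {
  setup <- fixture_eeg_setup(n_nodes = 40, n_refs = 2)
  lf <- compute_leadfields(setup$space, setup$eeg, setup$shells)
  expect_identical(perturb_leadfield(lf, 0, seed = 5)$gain, lf$gain)
  p1 <- perturb_leadfield(lf, 0.1, seed = 5)
  p2 <- perturb_leadfield(lf, 0.1, seed = 5)
  expect_identical(p1$gain, p2$gain)
  rel <- sqrt(sum((p1$gain - lf$gain)^2)) / sqrt(sum(lf$gain^2))
  expect_equal(rel, 0.1, tolerance = 1e-3)
  # common-average reference preserved under perturbation
  expect_lt(max(abs(colSums(p1$gain))) / max(abs(p1$gain)), 1e-12)
  # different seed, different field
  expect_gt(max(abs(perturb_leadfield(lf, 0.1, seed = 6)$gain - p1$gain)), 0)
  expect_error(perturb_leadfield(lf, -0.1, seed = 1), ">= 0")
})

test_that("leadfield stacks are linear in the dipole moment and indexable", {
  setup <- fixture_eeg_setup(n_nodes = 10, n_refs = 2)
  lf <- compute_leadfields(setup$space, setup$eeg, setup$shells)
  g <- lf_gain(lf, 3)
  expect_equal(dim(g), c(setup$eeg$n, 3))
  direct <- eeg_sphere_leadfield(setup$shells, setup$eeg, setup$space$node_positions[3, ])
  expect_equal(unname(g), unname(direct), tolerance = 1e-12)
})
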