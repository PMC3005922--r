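params <- default_plp_params()

test_that("plp_energy reproduces the trapezoidal well shape", {
  for (p in list(params$hbond, params$steric)) {
    expect_equal(plp_energy(0, p), p$V5)
    expect_equal(plp_energy((p$V1 + p$V2) / 2, p), p$V6 / 2)
    expect_equal(plp_energy((p$V2 + p$V3) / 2, p), p$V6)
    expect_equal(plp_energy(p$V4 + 0.01, p), 0)
    expect_equal(plp_energy(p$V4 + 100, p), 0)
  }
})

test_that("plp_energy is continuous at every breakpoint", {
  h <- 1e-12
  for (p in list(params$hbond, params$steric)) {
    for (bp in c(p$V1, p$V2, p$V3, p$V4)) {
      left <- plp_energy(bp - h, p)
      right <- plp_energy(bp + h, p)
      expect_lt(abs(left - right), 1e-9)
    }
  }
})

test_that("plp_energy attains its minimum V6 exactly on [V2, V3]", {
  for (p in list(params$hbond, params$steric)) {
    r <- seq(0, p$V4 + 2, by = 1e-3)
    e <- plp_energy(r, p)
    expect_equal(min(e), p$V6)
    at_min <- r[e == p$V6]
    expect_true(all(at_min >= p$V2 - 1e-9 & at_min <= p$V3 + 1e-9))
  }
})

test_that("invalid PLP parameters are rejected", {
  expect_error(plp_params(3, 2, 4, 5, 1, -1), "V1 < V2")
  expect_error(plp_params(1, 2, 3, 4, -1, -1), "V5")
  expect_error(plp_params(1, 2, 3, 4, 1, 1), "V6")
  expect_error(plp_energy(-0.5, params$hbond), "non-negative")
})

test_that("electrostatic energy is 332 q q / r inside the cutoff", {
  expect_equal(electrostatic_energy(1, -1, 3.32), -100.0)
  expect_equal(electrostatic_energy(0, -1, 3.32), 0)
  expect_equal(electrostatic_energy(1, 1, 13, cutoff = 12), 0)
  expect_equal(electrostatic_energy(2, 1, 2), 332)
  expect_error(electrostatic_energy(1, 1, 0), "degenerate")
})

test_that("pair classification needs one donor and one acceptor side", {
  expect_equal(classify_pair("donor", "acceptor"), "hbond")
  expect_equal(classify_pair("acceptor", "donor"), "hbond")
  expect_equal(classify_pair("both", "both"), "hbond")
  expect_equal(classify_pair("donor", "donor"), "steric")
  expect_equal(classify_pair("nonpolar", "acceptor"), "steric")
  expect_equal(classify_pair("nonpolar", "nonpolar"), "steric")
  # symmetric over all class pairs
  cls <- c("donor", "acceptor", "both", "nonpolar")
  for (a in cls) for (b in cls)
    expect_equal(classify_pair(a, b), classify_pair(b, a))
})

test_that("a pose beyond every cutoff yields an all-zero profile", {
  site <- toy_site()
  far <- toy_pose(dx = 100)
  prof <- atom_profile(site, far, params)
  expect_true(all(prof$energies == 0))
  expect_error(build_profile_matrix(list(prof)), "empty matrix")
})

test_that("atom_profile matches the brute-force double-loop oracle", {
  site <- toy_site()
  for (shift in list(c(0, 0), c(0.3, -0.2), c(1.1, 0.7))) {
    pose <- toy_pose(dx = shift[1], dy = shift[2])
    prof <- atom_profile(site, pose, params, es_cutoff = 12)
    expect_equal(prof$energies,
                 oracle_profile(site, pose, params, es_cutoff = 12),
                 tolerance = 1e-9)
  }
  # larger randomized complex
  spec <- synth_spec(seed = 9)
  rec <- make_receptor(spec)
  pose <- make_pose_set(spec, rec)$poses[[1]]
  prof <- atom_profile(rec, pose, params)
  expect_equal(prof$energies, oracle_profile(rec, pose, params),
               tolerance = 1e-9)
})

test_that("profiles are deterministic and invariant to atom reordering", {
  site <- toy_site()
  pose <- toy_pose()
  p1 <- atom_profile(site, pose, params)
  p2 <- atom_profile(site, pose, params)
  expect_identical(p1$energies, p2$energies)
  # ligand atom reordering leaves every E_j unchanged
  rev_pose <- pose
  rev_pose$atoms <- pose$atoms[2:1, ]
  rev_pose$bonds <- data.frame(i = 2L, j = 1L, order = 1L)
  p3 <- atom_profile(site, rev_pose, params)
  expect_equal(p3$energies, p1$energies)
  # receptor atom reordering permutes the profile keys only
  rev_site <- site
  rev_site$atoms <- site$atoms[2:1, ]
  p4 <- atom_profile(rev_site, pose, params)
  expect_equal(p4$energies[names(p1$energies)], p1$energies)
})

test_that("rigid translation of pose and site leaves the profile unchanged", {
  site <- toy_site(); pose <- toy_pose()
  ref <- atom_profile(site, pose, params)$energies
  shift <- c(13.7, -4.2, 8.8)
  site$atoms[, c("x", "y", "z")] <- site$atoms[, c("x", "y", "z")] +
    rep(shift, each = nrow(site$atoms))
  pose$atoms[, c("x", "y", "z")] <- pose$atoms[, c("x", "y", "z")] +
    rep(shift, each = nrow(pose$atoms))
  moved <- atom_profile(site, pose, params)$energies
  expect_equal(moved, ref, tolerance = 1e-9)
})

test_that("overlapping atoms raise a degenerate-geometry error", {
  site <- toy_site()
  pose <- toy_pose()
  pose$atoms$x[1] <- site$atoms$x[1]
  pose$atoms$y[1] <- site$atoms$y[1]
  pose$atoms$z[1] <- site$atoms$z[1]
  expect_error(atom_profile(site, pose, params), "degenerate geometry")
})

test_that("zero-column dropping matches an exhaustive scan and conserves values", {
  site <- toy_site()
  profs <- list(
    atom_profile(site, toy_pose(id = "a"), params),
    atom_profile(site, toy_pose(dx = 0.5, id = "b"), params),
    atom_profile(site, toy_pose(dx = 1, id = "c"), params))
  eps <- 1e-6
  pm <- build_profile_matrix(profs, epsilon = eps)
  raw <- do.call(rbind, lapply(profs, `[[`, "energies"))
  keep_oracle <- colnames(raw)[vapply(seq_len(ncol(raw)), function(j)
    any(abs(raw[, j]) >= eps), logical(1))]
  expect_equal(pm$atom_serials, keep_oracle)
  expect_equal(unname(pm$values), unname(raw[, keep_oracle, drop = FALSE]))
  expect_equal(pm$pose_ids, c("a", "b", "c"))

  # an atom touched by no pose is absent
  far_site <- toy_site()
  far_site$atoms <- rbind(far_site$atoms,
                          transform(far_site$atoms[2, ], serial = 99,
                                    x = 500))
  profs2 <- lapply(list("a", "b"), function(id)
    atom_profile(far_site, toy_pose(id = id), params))
  pm2 <- build_profile_matrix(profs2)
  expect_false("99" %in% pm2$atom_serials)

  # with no zero columns the matrix is unchanged
  expect_equal(dim(pm$values), c(3L, length(keep_oracle)))
  pm_again <- build_profile_matrix(profs, epsilon = eps)
  expect_identical(pm$values, pm_again$values)
})
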