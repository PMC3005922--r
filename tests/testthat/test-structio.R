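test_that("read_receptor strips hydrogens, resolves altLocs and keeps serials", {
  path <- write_fixture_pdb()
  site <- read_receptor(path)
  # 20 records - 2 hydrogens - 1 altLoc B duplicate
  expect_equal(nrow(site$atoms), 17)
  expect_false(any(site$atoms$element == "H"))
  # altLoc: only the A copy of GLU CB survives (serial 11, not 12)
  expect_true(11 %in% site$atoms$serial)
  expect_false(12 %in% site$atoms$serial)
  # serials preserved from the file
  expect_true(all(site$atoms$serial %in% c(1:5, 7:11, 13:16, 18:20)))
  # formal charge parsed from columns 79-80
  expect_equal(site$atoms$formal_charge[site$atoms$serial == 16], -1)
  expect_true(all(site$atoms$formal_charge[site$atoms$serial != 16] == 0))
})

test_that("read_receptor rejects unreadable and empty structures", {
  expect_error(read_receptor(tempfile()), "cannot read")
  empty <- tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(read_receptor(empty), "empty structure|parse")
})

test_that("receptor atoms get hydrogen-bond classes from the residue table", {
  site <- read_receptor(write_fixture_pdb())
  a <- site$atoms
  cls_of <- function(serial) a$hb_class[a$serial == serial]
  expect_equal(cls_of(1), "donor")      # backbone amide N
  expect_equal(cls_of(4), "acceptor")   # backbone carbonyl O
  expect_equal(cls_of(2), "nonpolar")   # CA carbon
  expect_equal(cls_of(16), "acceptor")  # GLU carboxylate O
  expect_equal(cls_of(20), "both")      # SER OG hydroxyl
})

test_that("read_poses returns heavy-atom poses in file order with energies", {
  path <- write_fixture_sdf()
  poses <- read_poses(path)
  expect_length(poses, 3)
  expect_equal(vapply(poses, `[[`, character(1), "pose_id"),
               c("pose1", "pose2", "pose3"))
  expect_equal(vapply(poses, `[[`, numeric(1), "docked_energy"),
               c(-8.1, -7.2, -9.0))
  # pose2 had 2 explicit hydrogens: they and their bonds are gone
  expect_equal(nrow(poses[[2]]$atoms), 2)
  expect_equal(nrow(poses[[2]]$bonds), 1)
  expect_false(any(poses[[2]]$atoms$element == "H"))
  # pose3 nitrogen charge from M CHG
  expect_equal(poses[[3]]$atoms$formal_charge[poses[[3]]$atoms$element == "N"],
               1)
})

test_that("missing energy fields error unless a default is supplied", {
  path <- write_fixture_sdf(energy_field = "other_name")
  expect_error(read_poses(path), "lacks energy field")
  poses <- read_poses(path, energy_field = "other_name")
  expect_equal(poses[[1]]$docked_energy, -8.1)
  poses <- read_poses(path, default_energy = 0)
  expect_equal(vapply(poses, `[[`, numeric(1), "docked_energy"), rep(0, 3))
})

test_that("ligand hb classes follow the valence rule table", {
  poses <- read_poses(write_fixture_sdf())
  # pose1: C-C=O, carbonyl O is an acceptor, carbons nonpolar
  expect_equal(poses[[1]]$atoms$hb_class, c("nonpolar", "nonpolar", "acceptor"))
  # pose2: C-N with one (stripped) H, amide-like N below valence -> donor
  expect_equal(poses[[2]]$atoms$hb_class[2], "donor")
  # pose3: N bonded to 4 heavy atoms with +1 charge: no implicit H slot
  # under valence 3+1... (4 single bonds = 4 = 3+1) -> charged N, donor
  n_row <- which(poses[[3]]$atoms$element == "N")
  expect_equal(poses[[3]]$atoms$hb_class[n_row], "donor")
})

test_that("assign_hb_classes warns on unknown elements and is idempotent", {
  atoms <- tscc:::new_atom_table(1:2, c("C", "Zz"), c(0, 2), 0, 0,
                                 residue_tag = "A:LIG:1")
  expect_warning(out <- assign_hb_classes(atoms), "unknown element")
  expect_equal(out$hb_class, c("nonpolar", "nonpolar"))
  expect_warning(again <- assign_hb_classes(out), "unknown element")
  expect_identical(again$hb_class, out$hb_class)
})

test_that("binding-site extraction is residue-level with a hard radius", {
  # residue 1 has one atom at 9.9 A and one at 14 A; residue 2 only at 10.1 A
  atoms <- tscc:::new_atom_table(
    1:3, c("C", "C", "C"), x = c(9.9, 14, 10.1), y = 0, z = 0,
    residue_tag = c("A:ALA:1", "A:ALA:1", "A:GLY:2"))
  atoms <- assign_hb_classes(atoms)
  rec <- receptor_site(atoms)
  lig <- toy_pose()
  lig$atoms$x <- c(0, 0); lig$atoms$y <- c(0, 0); lig$atoms$z <- c(0, 0)
  site <- extract_binding_site(rec, lig, radius = 10)
  # whole residue 1 in (any-atom rule), residue 2 out
  expect_equal(site$atoms$serial, c(1, 2))
  expect_error(extract_binding_site(rec, lig, radius = 5), "empty binding site")
  # radius large enough covers everything
  all_in <- extract_binding_site(rec, lig, radius = 100)
  expect_equal(nrow(all_in$atoms), 3)
})

test_that("binding-site extraction is monotone in the radius", {
  spec <- synth_spec(seed = 11)
  rec <- make_receptor(spec)
  lig <- make_pose_set(spec, rec)$poses[[1]]
  prev <- character(0)
  for (r in c(4, 6, 8, 12)) {
    site <- tryCatch(extract_binding_site(rec, lig, radius = r),
                     error = function(e) NULL)
    cur <- if (is.null(site)) character(0) else
      as.character(site$atoms$serial)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("PDB and SDF writers round-trip through the readers", {
  spec <- synth_spec(seed = 5)
  rec <- make_receptor(spec)
  pdb <- tempfile(fileext = ".pdb")
  write_receptor_pdb(rec, pdb)
  back <- read_receptor(pdb)
  expect_equal(nrow(back$atoms), nrow(rec$atoms))
  expect_equal(back$atoms$serial, rec$atoms$serial)
  expect_equal(back$atoms$element, rec$atoms$element)
  expect_equal(back$atoms$formal_charge, rec$atoms$formal_charge)
  expect_equal(back$atoms$x, rec$atoms$x, tolerance = 1e-3)

  poses <- make_pose_set(spec, rec)$poses[1:3]
  sdf <- tempfile(fileext = ".sdf")
  write_poses_sdf(poses, sdf)
  back <- read_poses(sdf)
  expect_equal(vapply(back, `[[`, character(1), "pose_id"),
               unname(vapply(poses, `[[`, character(1), "pose_id")))
  for (k in seq_along(poses)) {
    expect_equal(back[[k]]$atoms$element, poses[[k]]$atoms$element)
    expect_equal(back[[k]]$atoms$formal_charge,
                 poses[[k]]$atoms$formal_charge)
    expect_equal(back[[k]]$docked_energy, poses[[k]]$docked_energy,
                 tolerance = 1e-8)
    expect_equal(nrow(back[[k]]$bonds), nrow(poses[[k]]$bonds))
  }
})

test_that("pose and receptor constructors enforce their invariants", {
  atoms <- tscc:::new_atom_table(1:2, c("C", "C"), c(0, 1.5), 0, 0)
  atoms <- assign_hb_classes(atoms, bonds = data.frame(i = 1, j = 2, order = 1))
  expect_error(ligand_pose("p", atoms, data.frame(i = 1, j = 3, order = 1), -1),
               "missing atom")
  expect_error(ligand_pose("p", atoms, data.frame(i = 1, j = 1, order = 1), -1),
               "self-bonds")
  expect_error(ligand_pose("p", atoms, data.frame(i = 1, j = 2, order = 1), NaN),
               "finite")
  dup <- rbind(atoms, atoms)
  expect_error(receptor_site(dup), "unique")
})

test_that("MOL2 input is read with OpenBabel-derived formal charges", {
  mol2 <- tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "lig1", " 5 4 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1   0.0000  0.0000  0.0000 C.3   1 LIG 0.0000",
    "  2 N1   1.5000  0.0000  0.0000 N.4   1 LIG 1.0000",
    "  3 C2   2.6000  1.0000  0.0000 C.3   1 LIG 0.0000",
    "  4 C3   1.6000 -1.4000  0.3000 C.3   1 LIG 0.0000",
    "  5 C4   1.4000  0.9000 -1.0000 C.3   1 LIG 0.0000",
    "@<TRIPOS>BOND",
    "  1 1 2 1", "  2 2 3 1", "  3 2 4 1", "  4 2 5 1"), mol2)
  poses <- read_poses(mol2, default_energy = -4.5)
  expect_length(poses, 1)
  a <- poses[[1]]$atoms
  # quaternary-type nitrogen carries the +1 formal charge
  expect_equal(a$formal_charge[a$element == "N"], 1)
  # 3D coordinates survive the conversion
  expect_equal(a$x, c(0, 1.5, 2.6, 1.6, 1.4), tolerance = 1e-4)
  expect_equal(poses[[1]]$docked_energy, -4.5)
})
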