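test_that("complex parsing extracts residues and the selected ligand", {
  spec <- toy_pocket_spec()
  path <- tempfile(fileext = ".pdb")
  generate_toy_complex(spec$residues, spec$ligand, path)
  cx <- parse_complex(path, "LIG")
  expect_equal(sort(unique(cx$residues$residue_key)),
               c("A:GLU12", "A:LEU10", "A:SER11", "A:VAL13"))
  expect_equal(nrow(cx$ligand), 5L)
  cx2 <- parse_complex(path, "L:1") # chain:resno selector
  expect_equal(cx2$ligand, cx$ligand)

  expect_error(parse_complex(path, "HOH"), "expected exactly 1")
  expect_error(parse_complex(path, "XYZ"), "matches 0")
  expect_error(parse_complex(tempfile(), "LIG"), "not found")
})

test_that("hydrophobic contacts respect the distance cutoff and polarity", {
  at_4A <- parse_complex(write_pair_complex("C", "CD1", "C", 4.0), "LIG")
  expect_equal(detect_hydrophobic(at_4A), "A:LEU1")

  at_5A <- parse_complex(write_pair_complex("C", "CD1", "C", 5.0), "LIG")
  expect_equal(detect_hydrophobic(at_5A), character(0))

  # a polar ligand oxygen close to a carbon is not a hydrophobic contact
  polar <- parse_complex(write_pair_complex("C", "CD1", "O", 3.0), "LIG")
  expect_equal(detect_hydrophobic(polar), character(0))

  # fluorine counts as apolar on the ligand side
  fluor <- parse_complex(write_pair_complex("C", "CD1", "F", 4.2), "LIG")
  expect_equal(detect_hydrophobic(fluor), "A:LEU1")
})

test_that("hydrogen bonds need distance and, with explicit H, geometry", {
  hb_case <- function(h_xyz = NULL, acc_xyz, d_ok = TRUE) {
    atoms <- data.frame(name = "OG", element = "O", x = 0, y = 0, z = 0)
    if (!is.null(h_xyz)) {
      atoms <- rbind(atoms, data.frame(name = "HG", element = "H",
                                       x = h_xyz[1], y = h_xyz[2],
                                       z = h_xyz[3]))
    }
    path <- tempfile(fileext = ".pdb")
    generate_toy_complex(
      residues = list(list(chain = "A", resno = 1L, resname = "SER",
                           atoms = atoms)),
      ligand = list(atoms = data.frame(name = "O1", element = "O",
                                       x = acc_xyz[1], y = acc_xyz[2],
                                       z = acc_xyz[3])),
      path = path
    )
    detect_hbonds(parse_complex(path, "LIG"))
  }
  # 2.9 A, angle 180: flagged
  good <- hb_case(h_xyz = c(0.95, 0, 0), acc_xyz = c(2.9, 0, 0))
  expect_equal(good$direction, "donor_to_ligand")
  # 4.0 A: too far
  expect_equal(nrow(hb_case(h_xyz = c(0.95, 0, 0), acc_xyz = c(4, 0, 0))),
               0L)
  # ~3.05 A but 90-degree angle at H: rejected
  expect_equal(nrow(hb_case(h_xyz = c(0.95, 0, 0),
                            acc_xyz = c(0.95, 2.9, 0))), 0L)
  # donor without any explicit H is not a donor
  expect_equal(nrow(hb_case(h_xyz = NULL, acc_xyz = c(2.9, 0, 0))), 0L)
})

test_that("ligand donors are detected toward residue acceptors", {
  path <- tempfile(fileext = ".pdb")
  generate_toy_complex(
    residues = list(list(chain = "A", resno = 12L, resname = "GLU",
                         atoms = data.frame(name = "OE1", element = "O",
                                            x = 0, y = 0, z = 0))),
    ligand = list(atoms = data.frame(
      name = c("N1", "H1"), element = c("N", "H"),
      x = c(3.2, 2.2), y = 0, z = 0
    )),
    path = path
  )
  hb <- detect_hbonds(parse_complex(path, "LIG"))
  expect_equal(hb$residue_key, "A:GLU12")
  expect_equal(hb$direction, "acceptor_from_ligand")
})

test_that("fingerprints recover the planted pocket interactions exactly", {
  spec <- toy_pocket_spec()
  path <- tempfile(fileext = ".pdb")
  generate_toy_complex(spec$residues, spec$ligand, path)
  cx <- parse_complex(path, "LIG")
  expect_equal(detect_hydrophobic(cx), spec$expected$hydrophobic)
  expect_equal(detect_hbonds(cx), spec$expected$hbonds)
  fp <- build_plif(cx)
  expect_equal(rownames(fp)[fp[, "hydrophobic_contact"]], "A:LEU10")
  expect_equal(rownames(fp)[fp[, "hbond_donor_to_ligand"]], "A:SER11")
  expect_equal(rownames(fp)[fp[, "hbond_acceptor_from_ligand"]],
               "A:GLU12")
})

test_that("interactions are invariant under rigid-body transforms", {
  spec <- toy_pocket_spec()
  path <- tempfile(fileext = ".pdb")
  generate_toy_complex(spec$residues, spec$ligand, path)
  cx <- parse_complex(path, "LIG")
  fp0 <- build_plif(cx)
  set.seed(21)
  for (i in 1:8) {
    moved <- transform_complex(cx, random_rotation_matrix(),
                               stats::runif(3, -30, 30))
    expect_equal(build_plif(moved), fp0)
  }
  expect_error(transform_complex(cx, diag(3) * 2), "orthonormal")
})

test_that("fingerprint similarity is a proper Tanimoto on shared universes", {
  spec <- toy_pocket_spec()
  path <- tempfile(fileext = ".pdb")
  generate_toy_complex(spec$residues, spec$ligand, path)
  cx <- parse_complex(path, "LIG")
  fp <- build_plif(cx)
  expect_equal(plif_similarity(fp, fp), 1)

  fp_b <- fp
  fp_b[] <- FALSE
  fp_b["A:VAL13", "hydrophobic_contact"] <- TRUE
  expect_equal(plif_similarity(fp, fp_b), 0) # disjoint bit sets
  expect_equal(plif_similarity(fp_b, fp), plif_similarity(fp, fp_b))

  fp_c <- fp
  fp_c["A:GLU12", "hbond_acceptor_from_ligand"] <- FALSE # 2 of 3 shared
  expect_equal(plif_similarity(fp, fp_c), 2 / 3)

  fp_alien <- fp[-1, , drop = FALSE]
  class(fp_alien) <- class(fp)
  expect_error(plif_similarity(fp, fp_alien), "universe")
})
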