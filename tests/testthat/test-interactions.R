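# Complex parsing, H-bond and contact detection, fingerprints.

# A minimal hand-built complex: one alanine whose backbone carbonyl oxygen
# accepts a bond from a ligand N-H at chosen distance/angle.
planted_pair <- function(d = 2.9, angle_dev = 15) {
  # ligand N at origin, H along +x; acceptor O at distance d, rotated
  # angle_dev degrees away from the N-H axis (D-H...A = 180 - dev approx)
  th <- angle_dev * pi / 180
  rec <- data.frame(type = "ATOM",
                    name = c("N", "CA", "C", "O"),
                    resname = "ALA", chain = "A", resno = 135L,
                    x = c(8, 7, 6, d * cos(th)),
                    y = c(2, 1.5, 1, d * sin(th)),
                    z = 0, element = c("N", "C", "C", "O"))
  lig <- data.frame(type = "HETATM", name = c("C1", "N1", "H1"),
                    resname = "LIG", chain = "A", resno = 900L,
                    x = c(-1.4, 0, 1.0), y = 0, z = 0,
                    element = c("C", "N", "H"))
  parse_complex(make_pdb_lines(rbind(rec, lig)), "LIG")
}

test_that("a planted N-H...O pair is detected once at valid geometry", {
  hb <- find_hbonds(planted_pair(2.9, 15))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$residue, "Ala135")
  expect_equal(hb$distance, 2.9, tolerance = 1e-3)  # PDB stores 3 decimals
  # expected D-H...A angle from the planted coordinates
  h <- c(1, 0, 0)
  a <- 2.9 * c(cos(15 * pi / 180), sin(15 * pi / 180), 0)
  v1 <- -h
  v2 <- a - h
  want <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(hb$angle, want, tolerance = 1e-3)
  expect_gt(hb$angle, 150)
  expect_equal(hb$direction, "ligand-donor")
})

test_that("distance and angle cutoffs reject near-miss geometries", {
  expect_equal(nrow(find_hbonds(planted_pair(3.6, 0), d_max = 3.5)), 0)
  expect_equal(nrow(find_hbonds(planted_pair(3.4, 0), d_max = 3.5)), 1)
  # D-H...A of 110 degrees fails the 120 degree default
  expect_equal(nrow(find_hbonds(planted_pair(2.9, 70))), 0)
})

test_that("contact shell respects the radius boundary", {
  mk <- function(d) {
    rec <- data.frame(type = "ATOM", name = "CB", resname = "LEU",
                      chain = "A", resno = 70L, x = d, y = 0, z = 0,
                      element = "C")
    lig <- data.frame(type = "HETATM", name = "C1", resname = "LIG",
                      chain = "A", resno = 900L, x = 0, y = 0, z = 0,
                      element = "C")
    parse_complex(make_pdb_lines(rbind(rec, lig)), "LIG")
  }
  expect_equal(contact_residues(mk(4.99), radius = 5), "Leu70")
  expect_equal(contact_residues(mk(5.01), radius = 5), character())
})

test_that("ambiguous ligand selectors and altloc records are handled", {
  rec <- data.frame(type = "ATOM", name = "CA", resname = "GLY", chain = "A",
                    resno = 1L, x = 10, y = 0, z = 0, element = "C")
  two_lig <- rbind(
    data.frame(type = "HETATM", name = "C1", resname = "LIG", chain = "A",
               resno = 900L, x = 0, y = 0, z = 0, element = "C"),
    data.frame(type = "HETATM", name = "C1", resname = "LIG", chain = "A",
               resno = 901L, x = 1, y = 0, z = 0, element = "C"))
  expect_error(parse_complex(make_pdb_lines(rbind(rec, two_lig)), "LIG"),
               "matches 2")
  expect_error(parse_complex(make_pdb_lines(rbind(rec, two_lig)), "XYZ"),
               "no ligand")
  one <- parse_complex(make_pdb_lines(rbind(rec, two_lig)),
                       list(resname = "LIG", resno = 901))
  expect_equal(nrow(one$ligand), 1)
  expect_equal(one$ligand$x, 1)

  # altloc: highest occupancy wins; ties go to A
  alt <- data.frame(type = c("ATOM", "ATOM", "ATOM"),
                    name = c("CA", "CB", "CB"), alt = c(" ", "A", "B"),
                    resname = "ALA", chain = "A", resno = 5L,
                    x = c(0, 1, 2), y = 0, z = 0,
                    occ = c(1, 0.4, 0.6),
                    element = c("C", "C", "C"))
  lig <- data.frame(type = "HETATM", name = "C1", alt = " ", resname = "LIG",
                    chain = "A", resno = 900L, x = 3, y = 0, z = 0, occ = 1,
                    element = "C")
  cx <- parse_complex(make_pdb_lines(rbind(alt, lig)), "LIG")
  cb <- cx$receptor[gsub("\\s", "", cx$receptor$elety) == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 2)  # occupancy 0.6 copy

  alt$occ <- c(1, 0.5, 0.5)
  cx <- parse_complex(make_pdb_lines(rbind(alt, lig)), "LIG")
  cb <- cx$receptor[gsub("\\s", "", cx$receptor$elety) == "CB", ]
  expect_equal(cb$x, 1)  # tie -> altloc A
})

test_that("generated complexes are recovered exactly and match the oracles", {
  specs <- list(list(h = 3, hr = 3, c = 5, d = 4),
                list(h = 4, hr = 2, c = 3, d = 2),
                list(h = 0, hr = 0, c = 4, d = 3),
                list(h = 6, hr = 6, c = 0, d = 5),
                list(h = 2, hr = 1, c = 6, d = 0))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sc <- synthetic_complex(seed = 100 + i, n_hbonds = sp$h,
                            n_hbond_residues = sp$hr, n_contacts = sp$c,
                            n_decoys = sp$d)
    cx <- parse_complex(sc$pdb, "LIG")
    expect_equal(nrow(cx$ligand), sc$truth$n_ligand_atoms)
    fp <- fingerprint(cx)
    expect_equal(fp$n_hbonds, sc$truth$n_hbonds)
    expect_setequal(fp$hbond_residues, sc$truth$hbond_residues)
    expect_setequal(fp$hydrophobic_residues, sc$truth$hydrophobic_residues)
    expect_length(intersect(fp$hydrophobic_residues,
                            sc$truth$decoy_residues), 0)
    # exhaustive all-pairs oracles
    hb <- find_hbonds(cx)
    expect_equal(sort(hb$residue), sort(oracle_hbonds(cx)))
    expect_setequal(contact_residues(cx), oracle_contacts(cx))
  }
})

test_that("fingerprints are invariant under rigid rotation + translation", {
  sc <- synthetic_complex(seed = 21, n_hbonds = 3, n_contacts = 4,
                          n_decoys = 3)
  cx <- parse_complex(sc$pdb, "LIG")
  fp <- fingerprint(cx)
  rot <- rotate_complex(cx, random_rotation(9), shift = c(5, -3, 2))
  fp_rot <- fingerprint(rot)
  expect_equal(fp_rot$n_hbonds, fp$n_hbonds)
  expect_setequal(fp_rot$hbond_residues, fp$hbond_residues)
  expect_setequal(fp_rot$hydrophobic_residues, fp$hydrophobic_residues)
  hb1 <- find_hbonds(cx)
  hb2 <- find_hbonds(rot)
  expect_equal(hb2$distance, hb1$distance, tolerance = 1e-6)
  expect_equal(hb2$angle, hb1$angle, tolerance = 1e-6)
})

test_that("enlarging the cutoffs never removes a hit", {
  sc <- synthetic_complex(seed = 33, n_hbonds = 2, n_contacts = 5,
                          n_decoys = 4)
  cx <- parse_complex(sc$pdb, "LIG")
  for (r in c(4, 5, 6, 7, 9)) {
    small <- contact_residues(cx, radius = r)
    big <- contact_residues(cx, radius = r + 1)
    expect_true(all(small %in% big))
  }
  for (d in c(3.0, 3.5, 4.0)) {
    small <- find_hbonds(cx, d_max = d)$residue
    big <- find_hbonds(cx, d_max = d + 0.5)$residue
    expect_true(all(small %in% big))
  }
})

test_that("apolar ligands and empty interfaces yield empty fingerprints", {
  sc <- synthetic_complex(seed = 5, n_hbonds = 0, n_contacts = 5,
                          n_decoys = 2)
  fp <- fingerprint(parse_complex(sc$pdb, "LIG"))
  expect_equal(fp$n_hbonds, 0)
  expect_gt(length(fp$hydrophobic_residues), 0)

  far <- synthetic_complex(seed = 6, n_hbonds = 0, n_contacts = 0,
                           n_decoys = 3)
  fp <- fingerprint(parse_complex(far$pdb, "LIG"))
  expect_equal(fp$n_hbonds, 0)
  expect_length(fp$hydrophobic_residues, 0)
})

test_that("exclusive-hydrophobic mode removes H-bond partners", {
  sc <- synthetic_complex(seed = 44, n_hbonds = 3, n_contacts = 4)
  cx <- parse_complex(sc$pdb, "LIG")
  fp <- fingerprint(cx, mode = "exclusive-hydrophobic")
  expect_length(intersect(fp$hydrophobic_residues, fp$hbond_residues), 0)
})

test_that("fingerprint similarity is the Jaccard index over residue sets", {
  f <- function(hb, hy) list(hbond_residues = hb, hydrophobic_residues = hy)
  expect_equal(compare_fingerprints(f("Ile62", "Val135"),
                                    f("Ile62", "Val135")), 1)
  expect_equal(compare_fingerprints(f("Ile62", character()),
                                    f("Gln185", character())), 0)
  expect_equal(compare_fingerprints(f(c("Ile62", "Val135"), character()),
                                    f(c("Ile62", "Gln185", "Val135"),
                                      character())), 2 / 3)
  expect_equal(compare_fingerprints(f(character(), character()),
                                    f(character(), character())), 1)
})
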