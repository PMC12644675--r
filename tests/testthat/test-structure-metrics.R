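test_that("PDB reading round-trips models and splits chains", {
  f <- withr::local_tempfile(fileext = ".pdb")
  two <- rbind(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
               atom_row("A", 1, "GLY", "N", "N", 1.3, 0, 0))
  write_pdb_fixture(two, f)
  m <- read_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(length(unique(m$chain)), 1)
  expect_equal(m$elesy, c("C", "N"))

  tri <- generate_symmetric_trimer(n_residues = 5)
  g <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_fixture(tri$model, g)
  m2 <- read_structure(g)
  expect_equal(sort(unique(m2$chain)), c("A", "B", "C"))
  expect_equal(nrow(m2), nrow(tri$model))
  expect_equal(ca_distance_stats(m2)$total_sum,
               ca_distance_stats(tri$model)$total_sum, tolerance = 1e-3)
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
})

test_that("contact classification respects the cutoff boundary", {
  base <- rbind(atom_row("A", 1, "ALA", "CB", "C", 0, 0, 0),
                atom_row("B", 1, "ALA", "CB", "C", 3.9, 0, 0))
  ct <- classify_contacts(structure_model(base))
  expect_equal(ct$summary$inter[ct$summary$type == "vdW"], 1)
  far <- base; far$x[2] <- 4.1
  ct2 <- classify_contacts(structure_model(far))
  expect_equal(ct2$summary$inter[ct2$summary$type == "vdW"], 0)
  # same-chain neighbors are excluded, distant residues are not
  sc <- rbind(atom_row("A", 1, "ALA", "CB", "C", 0, 0, 0),
              atom_row("A", 2, "ALA", "CB", "C", 3, 0, 0),
              atom_row("A", 5, "ALA", "CB", "C", 1.5, 2.5, 0))
  ct3 <- classify_contacts(structure_model(sc))
  expect_equal(ct3$summary$total[ct3$summary$type == "vdW"], 2)
  expect_true(all(ct3$pairs$scope == "intra"))
})

test_that("salt bridges pair carboxylates with basic nitrogens across chains", {
  m <- structure_model(rbind(
    atom_row("A", 5, "GLU", "OE1", "O", 0, 0, 0),
    atom_row("B", 9, "LYS", "NZ", "N", 3.5, 0, 0),
    atom_row("B", 9, "LYS", "CE", "C", 4.6, 0, 0)))
  ct <- classify_contacts(m)
  sb <- ct$summary[ct$summary$type == "salt bridge", ]
  expect_equal(sb$inter, 1)
  expect_equal(sb$intra, 0)
  # the same O-N pair also counts as a polar heavy-atom hydrogen bond at 3.5 A
  hb <- ct$summary[ct$summary$type == "hydrogen bond", ]
  expect_equal(hb$inter, 1)
  # two acidic oxygens do not form a salt bridge with each other
  m2 <- structure_model(rbind(
    atom_row("A", 5, "GLU", "OE1", "O", 0, 0, 0),
    atom_row("B", 7, "ASP", "OD1", "O", 3.0, 0, 0)))
  ct2 <- classify_contacts(m2)
  expect_equal(ct2$summary$total[ct2$summary$type == "salt bridge"], 0)
})

test_that("contact counts equal a brute-force all-pairs oracle", {
  tri <- generate_symmetric_trimer(n_residues = 8, ca_distance = 3.6,
                                   rise = 1.2, twist = 25)
  ct <- classify_contacts(tri$model)
  vdw <- ct$summary[ct$summary$type == "vdW", ]
  oracle <- brute_force_contacts(tri$model, 4.0, elements = "C")
  expect_gt(oracle$inter, 0)   # fixture actually has interchain contacts
  expect_gt(oracle$intra, 0)
  expect_equal(vdw$intra, oracle$intra)
  expect_equal(vdw$inter, oracle$inter)
  expect_equal(vdw$total, vdw$intra + vdw$inter)
})

test_that("contacts are invariant under chain relabeling and rigid motion", {
  tri <- generate_symmetric_trimer(n_residues = 6, ca_distance = 3.6, twist = 30)
  ref <- classify_contacts(tri$model)$summary
  relab <- tri$model
  relab$chain <- c(A = "C", B = "A", C = "B")[relab$chain]
  expect_equal(classify_contacts(structure_model(relab))$summary, ref)
  # rigid rotation about x plus translation
  th <- 0.7
  rot <- tri$model
  y <- rot$y * cos(th) - rot$z * sin(th)
  z <- rot$y * sin(th) + rot$z * cos(th)
  rot$y <- y + 11; rot$z <- z - 4; rot$x <- rot$x + 2
  expect_equal(classify_contacts(structure_model(rot))$summary, ref)
})

test_that("interchain C-alpha statistics have the closed-form sum", {
  tri <- generate_symmetric_trimer(n_residues = 27, ca_distance = 4.5)
  st <- ca_distance_stats(tri$model)
  expect_equal(st$total_sum, 27 * 3 * 4.5, tolerance = 1e-9)
  # rotational symmetry: the three per-position distances are equal
  expect_true(all(abs(st$per_position$sd) < 1e-9))
  expect_true(all(abs(st$per_position$mean - 4.5) < 1e-9))
  # chain-count and matching errors
  twoch <- tri$model[tri$model$chain != "C", ]
  expect_error(ca_distance_stats(structure_model(twoch)), "3 chains")
  chopped <- tri$model[!(tri$model$chain == "B" & tri$model$resno == 27), ]
  expect_error(ca_distance_stats(structure_model(chopped)), "unpaired")
})

test_that("SASA matches analytic spheres and is occlusion-monotone", {
  one <- structure_model(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0))
  s1 <- sasa(one, n_sphere_points = 2000)
  expect_equal(s1$total, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-3)
  # two atoms far apart: additive
  far <- structure_model(rbind(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
                               atom_row("A", 5, "GLY", "CA", "C", 100, 0, 0)))
  expect_equal(sasa(far, n_sphere_points = 500)$total,
               2 * sasa(one, n_sphere_points = 500)$total, tolerance = 1e-9)
  # moving atoms closer cannot increase the area
  dists <- c(20, 6, 3, 1.5)
  areas <- vapply(dists, function(d) {
    m <- structure_model(rbind(atom_row("A", 1, "GLY", "CA", "C", 0, 0, 0),
                               atom_row("A", 5, "GLY", "CA", "C", d, 0, 0)))
    sasa(m, n_sphere_points = 500)$total
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-9))
  # unknown element is a named error
  bad <- structure_model(atom_row("A", 1, "UNK", "FE", "FE", 0, 0, 0))
  expect_error(sasa(bad), "FE")
  # deterministic for fixed quadrature
  tri <- generate_symmetric_trimer(n_residues = 4)$model
  expect_identical(sasa(tri)$total, sasa(tri)$total)
})
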