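# Independent element masses typed fresh from the isotope tables, so the
# residue-table consistency check does not reuse the package's constants.
.iso <- c(C = 12.0, H = 1.00782503, N = 14.00307401, O = 15.99491462,
          S = 31.97207069)

test_that("residue table is internally consistent and complete", {
  tab <- residue_table()
  expect_true(all(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")] %in% tab$token))
  recomputed <- with(tab, C * .iso["C"] + H * .iso["H"] + N * .iso["N"] +
                       O * .iso["O"] + S * .iso["S"])
  expect_true(all(abs(recomputed - tab$monoisotopic_mass) < 1e-4))
  # non-natural residues have the stated compositions
  nal <- tab[tab$token == "Nal", ]
  expect_equal(unlist(nal[, c("C", "H", "N", "O", "S")]),
               c(C = 13, H = 11, N = 1, O = 1, S = 0), ignore_attr = TRUE)
  dip <- tab[tab$token == "Dip", ]
  expect_equal(unlist(dip[, c("C", "H", "N", "O", "S")]),
               c(C = 15, H = 13, N = 1, O = 1, S = 0), ignore_attr = TRUE)
})

test_that("sequence parsing handles stereo flags, braces and termini", {
  s0 <- parse_sequence("H-GYIPEAPRDGQAYVRKDGEWVLLSTFL-OH")
  expect_length(s0$residues, 27)
  expect_identical(s0$c_terminus, "acid")
  expect_true(all(s0$stereo == "L"))

  s6 <- parse_sequence("H-{Dip}IPEAPRDaQAYVRKfGEWVLLSTFL-NH2")
  expect_length(s6$residues, 26)
  expect_identical(s6$residues[1], "Dip")
  expect_identical(s6$c_terminus, "amide")
  expect_identical(s6$stereo[9], "D")    # position 10 of the parent numbering
  expect_identical(s6$residues[9], "A")  # D-alanine maps to the Ala row

  g <- parse_sequence("H-G-OH")
  expect_length(g$residues, 1)
  expect_identical(g$residues, "G")

  expect_error(parse_sequence("H-GXZ1-OH"), "position")
  expect_error(parse_sequence("H-G{Foo}G-OH"), "Foo")
  expect_error(parse_sequence(""), "non-empty")
})

test_that("monoisotopic mass and formula of glycine are exact", {
  expect_equal(monoisotopic_mass("H-G-OH"), 75.03203, tolerance = 1e-7)
  f <- molecular_formula("H-G-OH")
  expect_equal(f[["C"]], 2)
  expect_equal(f[["H"]], 5)
  expect_equal(f[["N"]], 1)
  expect_equal(f[["O"]], 2)
  expect_equal(attr(f, "atom_count"), 10)
  expect_equal(oligomer_mz("H-G-OH", 1, 1), 76.039, tolerance = 1e-3)
})

test_that("the amide C-terminus shifts the mass by -0.98402 u", {
  acid <- monoisotopic_mass("H-GEWVLLSTFL-OH")
  amide <- monoisotopic_mass("H-GEWVLLSTFL-NH2")
  expect_equal(amide - acid, -0.98402, tolerance = 1e-4)
})

test_that("published trimer 5+ m/z and atom counts reproduce for all variants", {
  ref <- published_trimer_table()
  tab <- mass_table(foldon_sequences(), n_mer = 3, z = 5)
  expect_equal(tab$mz, ref$mz, tolerance = 0.01 / 1800)
  expect_identical(tab$atoms_nmer, as.integer(ref$atoms))
  # trimer count/mass exactly 3x the monomer
  expect_identical(tab$atoms_nmer, 3L * tab$atoms_monomer)
  for (nm in names(foldon_sequences())) {
    p <- parse_sequence(foldon_sequences()[[nm]])
    expect_equal(3 * monoisotopic_mass(p),
                 sum(molecular_formula(p, n_mer = 3) *
                       c(12.0, 1.00782503, 14.00307401, 15.99491462, 31.97207069)),
                 tolerance = 1e-3)
  }
})

test_that("D-stereochemistry is mass neutral (lowercase equals uppercase)", {
  seqs <- foldon_sequences()
  expect_equal(monoisotopic_mass(seqs[["foldon1"]]),
               monoisotopic_mass(seqs[["foldon2"]]))
  expect_equal(monoisotopic_mass(seqs[["foldon3"]]),
               monoisotopic_mass(seqs[["foldon4"]]))
  expect_identical(molecular_formula(seqs[["foldon1"]]),
                   molecular_formula(seqs[["foldon2"]]))
})

test_that("oligomer m/z follows the proton bookkeeping and rejects z = 0", {
  p <- parse_sequence("H-GY-OH")
  m <- monoisotopic_mass(p)
  for (n in 1:3) for (z in 1:5)
    expect_equal(oligomer_mz(p, n, z), (n * m + z * 1.00728) / z)
  expect_error(oligomer_mz(p, 1, 0), "neutral")
  # difference oracle: variant 1 monomer = variant 0 + (A-G) + (F-D) - amide shift
  tabs <- residue_table()
  dm <- with(tabs, monoisotopic_mass[token == "A"] - monoisotopic_mass[token == "G"] +
               monoisotopic_mass[token == "F"] - monoisotopic_mass[token == "D"]) - 0.98402
  expect_equal(monoisotopic_mass(foldon_sequences()[["foldon1"]]),
               monoisotopic_mass(foldon_sequences()[["foldon0"]]) + dm,
               tolerance = 1e-4)
})

test_that("user-supplied residues extend the table", {
  tab <- residue_table(custom_residues = list(Hot = c(C = 4, H = 7, N = 1, O = 3)))
  expect_true("Hot" %in% tab$token)
  s <- parse_sequence("H-G{Hot}G-OH",
                      custom_residues = list(Hot = c(C = 4, H = 7, N = 1, O = 3)))
  expect_length(s$residues, 3)
})
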