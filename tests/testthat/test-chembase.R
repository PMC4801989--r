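# formula arithmetic, element masses, residue database and registration

test_that("formula_mass matches hand-derived values and the empty formula is 0", {
  expect_identical(formula_mass(chem_formula()), 0)
  expect_equal(formula_mass("H2O"), 18.0106, tolerance = 1e-4)
  expect_equal(formula_mass("C2H3NO"), 57.0215, tolerance = 1e-4)
  expect_identical(unname(element_masses()["C"]), 12)
  expect_error(formula_mass(chem_formula(Xx = 1)), "Xx")
})

test_that("parse_formula handles counts, rejects bad input, and round-trips", {
  expect_identical(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  expect_identical(unclass(parse_formula("C5H9NO")),
                   c(C = 5L, H = 9L, N = 1L, O = 1L))
  expect_error(parse_formula("C0H2"), "count must be >= 1")
  expect_error(parse_formula("C5H9xNO"), "position")
  expect_error(parse_formula(""), "empty")
  # Hill-order serialization round-trips
  for (txt in c("H2O", "C5H9NO", "C13H17O3S", "NaCl", "C6H12N4O")) {
    f <- parse_formula(txt)
    expect_true(parse_formula(format(f)) == f)
  }
  expect_identical(format(parse_formula("OH2")), "H2O")  # no C: alphabetical
  expect_identical(format(parse_formula("NOC2H3")), "C2H3NO")
})

test_that("formula arithmetic is commutative, associative and invertible", {
  set.seed(7)
  pool <- c("C2H3NO", "C6H12N4O", "H2O", "C13H17O3S", "C5H9O2S", "NaCl")
  for (i in 1:25) {
    a <- parse_formula(sample(pool, 1))
    b <- parse_formula(sample(pool, 1))
    c <- parse_formula(sample(pool, 1))
    expect_true((a + b) == (b + a))
    expect_true(((a + b) + c) == (a + (b + c)))
    expect_true(((a + b) - b) == a)
    expect_equal(formula_mass(a + b), formula_mass(a) + formula_mass(b),
                 tolerance = 1e-9)
  }
  expect_error(parse_formula("H2O") - parse_formula("C"), "negative")
})

test_that("residue lookup resolves known codes and reports near-misses", {
  expect_true(lookup_residue("G", "peptide")$formula == parse_formula("C2H3NO"))
  expect_identical(lookup_residue("pS", "peptide")$name, "phosphoserine")
  expect_false(lookup_residue("pS", "peptide")$canonical)
  err <- tryCatch(lookup_residue("Zz", "peptide"), error = conditionMessage)
  expect_match(err, "unknown peptide residue code 'Zz'")
  # case-sensitive codes: "pA" is unknown but one substitution from pS/pT/pY
  expect_error(lookup_residue("pA", "peptide"), "nearest matches.*pS")
  expect_error(lookup_residue("g", "peptide"), "unknown")
})

test_that("the seed database covers the documented entries with correct masses", {
  # independent reference: residue masses from published most-abundant-isotope
  # atomic masses (computed outside this package), u
  ref_peptide <- c(
    A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00918,
    E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
    L = 113.08406, K = 128.09496, M = 131.04048, F = 147.06841, P = 97.05276,
    S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841,
    pS = 166.99836, pT = 181.01401, pY = 243.02966, Nle = 113.08406,
    Orn = 114.07931, Cit = 157.08513)
  ref_peptoid <- c(
    Nme = 71.03711, Net = 85.05276, Npr = 99.06841, Nbu = 113.08406,
    Npm = 147.06841, Npe = 161.08406, Nspe = 161.08406, Nae = 100.06366,
    Nab = 128.09496, Nce = 129.04259, Nhe = 101.04768)
  for (code in names(ref_peptide)) {
    expect_equal(formula_mass(lookup_residue(code, "peptide")$formula),
                 ref_peptide[[code]], tolerance = 1e-4, label = code)
  }
  for (code in names(ref_peptoid)) {
    expect_equal(formula_mass(lookup_residue(code, "peptoid")$formula),
                 ref_peptoid[[code]], tolerance = 1e-4, label = code)
  }
  canon <- vapply(names(ref_peptide), function(code)
    lookup_residue(code, "peptide")$canonical, logical(1))
  expect_identical(sum(canon), 20L)
  expect_gte(length(ref_peptoid), 10L)

  ref_mods <- c(Na = 21.98194, K = 37.95588, Pbf = 252.08202,
                Boc = 100.05243, tBu = 56.06260, Trt = 242.10955)
  mods <- modification_table()
  expect_setequal(names(mods), names(ref_mods))
  for (nm in names(ref_mods)) {
    expect_equal(pepkit:::modification_delta_mass(mods[[nm]]), ref_mods[[nm]],
                 tolerance = 1e-4, label = nm)
  }
})

test_that("termini reconstitute the free peptide and support custom formulas", {
  nt <- resolve_terminus("unmodified", "N")
  ct <- resolve_terminus("acid", "C")
  expect_true((nt$delta + ct$delta) == parse_formula("H2O"))
  thio <- resolve_terminus("ethyl 3-mercaptopropionate thioester", "C")
  expect_true(thio$predefined)
  expect_equal(formula_mass(thio$delta), 133.03233, tolerance = 1e-4)
  custom <- resolve_terminus("C2H3O", "N")
  expect_false(custom$predefined)
  expect_true(custom$delta == parse_formula("C2H3O"))
  expect_error(resolve_terminus("no such terminus!", "C"), "predefined")
})

test_that("register_residue extends the database and enforces invariants", {
  on.exit(reset_database())
  register_residue("Nxx", "peptoid", "C7H13NO")
  expect_true(lookup_residue("Nxx", "peptoid")$formula == parse_formula("C7H13NO"))
  # immediately usable by the parser and calculators
  s <- parse_peptoid("Nme-Nxx")
  expect_equal(length(s), 2L)
  expect_equal(molecular_weight(s),
               formula_mass("C3H5NO") + formula_mass("C7H13NO") +
                 formula_mass("H2O"), tolerance = 1e-9)
  expect_error(register_residue("G", "peptide", "C2H3NO"), "already present")
  expect_error(register_residue("Zq", "peptide", chem_formula()), "non-empty")
  expect_error(register_residue("Z q", "peptide", "CH2"), "whitespace")
})
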