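# iterative-deepening mass spectral peak assignment

test_that("iteration caps step down with sequence length", {
  expect_identical(iteration_cap(1), 5L)
  expect_identical(iteration_cap(30), 5L)
  expect_identical(iteration_cap(31), 4L)
  expect_identical(iteration_cap(60), 4L)
  expect_identical(iteration_cap(61), 3L)
  expect_identical(iteration_cap(150), 3L)
  expect_error(iteration_cap(151))
})

test_that("deletion enumeration yields compositional multisets with the null entry", {
  s <- parse_peptide("AAG")
  d1 <- enumerate_deletions(s, 1)
  expect_equal(length(d1), 3L)  # {}, {A}, {G}
  d2 <- enumerate_deletions(s, 2)
  expect_equal(length(d2), 5L)  # adds {A,A}, {A,G}
  keys <- sort(vapply(d2, function(x) cand_key(x, integer(0)), character(1)))
  expect_identical(keys, sort(c("|", "A|", "G|", "A+A|", "A+G|")))
  expect_equal(length(enumerate_deletions(s, 0)), 1L)
  # multiplicity never exceeds the sequence composition
  expect_true(all(vapply(enumerate_deletions(s, 5), function(x)
    all(x <= table(s$codes)[names(x)]), logical(1))))
})

test_that("modification enumeration respects site licensing", {
  no_arg <- parse_peptide("GAG")
  only_pbf <- modification_table("Pbf")
  expect_equal(length(enumerate_modifications(no_arg, 2, only_pbf)), 1L)  # {} only
  one_arg <- parse_peptide("GRG")
  m <- enumerate_modifications(one_arg, 2, only_pbf)
  expect_equal(length(m), 2L)  # {} and {Pbf}; no double Pbf for a single Arg
  metals <- enumerate_modifications(no_arg, 1, modification_table("Na"))
  expect_equal(length(metals), 2L)  # {} and {Na}
  # Boc is licensed by the free N-terminus even without Lys/Trp
  boc_free <- enumerate_modifications(
    parse_peptide("GAG", n_term = "acetyl"), 1, modification_table("Boc"))
  expect_equal(length(boc_free), 1L)
  boc_nterm <- enumerate_modifications(no_arg, 1, modification_table("Boc"))
  expect_equal(length(boc_nterm), 2L)
})

test_that("candidate masses follow deletion/adduct arithmetic", {
  s <- parse_peptide("GAG")
  expect_equal(candidate_mass(s), molecular_weight(s), tolerance = 1e-12)
  expect_equal(candidate_mass(s, "A"), 132.0535, tolerance = 1e-4)
  expect_equal(candidate_mass(s, character(0), "Na") - candidate_mass(s),
               21.9819, tolerance = 1e-4)
  expect_error(candidate_mass(s, c("A", "A")), "cannot delete")
  expect_error(candidate_mass(s, "Z"), "cannot delete")
})

test_that("peak assignment matches the documented three-peak example", {
  s <- parse_peptide("GAG")
  rep <- assign_peaks(s, c(203.1, 132.05, 500.0))
  e1 <- rep$peaks[[1]]
  expect_true(e1$assigned)
  expect_identical(e1$iteration, 1L)
  expect_identical(report_keys(e1), "|")  # the full sequence
  expect_lt(e1$candidates[[1]]$delta, 0.011)
  e2 <- rep$peaks[[2]]
  expect_identical(report_keys(e2), "A|")
  expect_equal(e2$candidates[[1]]$mass, 132.0535, tolerance = 1e-4)
  expect_false(rep$peaks[[3]]$assigned)
  expect_error(assign_peaks(s, numeric(0)), "at least one")
  expect_error(assign_peaks(s, c(100, -5)), "positive")
})

test_that("engine candidate sets equal the flat exhaustive oracle", {
  # 30 random sequences here; the 100-sequence sweep runs in acceptance
  set.seed(43)
  for (i in 1:30) {
    s <- if (i %% 2 == 0) {
      parse_peptide(random_peptide_string(sample(3:8, 1)))
    } else {
      parse_peptoid(paste(sample(PEPTOID_CODES, sample(3:8, 1), replace = TRUE),
                          collapse = "-"))
    }
    mw <- molecular_weight(s)
    peaks <- pmax(1, mw + runif(sample(1:4, 1), -300, 60))
    got <- assign_peaks(s, peaks)
    want <- oracle_assign(s, peaks)
    for (k in seq_along(peaks)) {
      expect_identical(got$peaks[[k]]$assigned, want[[k]]$assigned)
      if (want[[k]]$assigned) {
        expect_identical(got$peaks[[k]]$iteration, as.integer(want[[k]]$iteration))
        expect_identical(report_keys(got$peaks[[k]]), want[[k]]$keys)
      }
    }
  }
})

test_that("assignment is monotone in the iteration budget", {
  set.seed(47)
  for (i in 1:10) {
    s <- parse_peptide(random_peptide_string(8))
    peaks <- pmax(1, molecular_weight(s) + runif(3, -250, 30))
    assigned_by_n <- lapply(1:3, function(n) {
      r <- assign_peaks(s, peaks, max_iterations = n)
      which(vapply(r$peaks, `[[`, logical(1), "assigned"))
    })
    expect_true(all(assigned_by_n[[1]] %in% assigned_by_n[[2]]))
    expect_true(all(assigned_by_n[[2]] %in% assigned_by_n[[3]]))
  }
})

test_that("every reported candidate satisfies its own invariants", {
  set.seed(53)
  for (i in 1:10) {
    s <- parse_peptide(random_peptide_string(7))
    peaks <- pmax(1, molecular_weight(s) + runif(3, -250, 30))
    rep <- assign_peaks(s, peaks)
    comp <- table(s$codes)
    for (e in rep$peaks) {
      for (cand in e$candidates) {
        expect_lte(cand$delta, rep$tolerance)
        if (length(cand$deletions)) {
          expect_true(all(cand$deletions <= comp[names(cand$deletions)]))
        }
      }
    }
  }
})

test_that("the candidate budget guardrail aborts instead of exhausting memory", {
  s <- parse_peptide(random_peptide_string(20))
  expect_error(assign_peaks(s, molecular_weight(s), budget = 10),
               "candidate budget exceeded")
})

test_that("assignment TSV export mirrors the report", {
  s <- parse_peptide("GAG")
  rep <- assign_peaks(s, c(203.1, 500))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignment_tsv(rep, path)
  tab <- read.delim(path, colClasses = "character")
  expect_identical(names(tab), c("peak_mz", "deletions", "adducts",
                                 "calculated_mass", "delta", "iteration"))
  expect_equal(nrow(tab), 2L)
  df <- as.data.frame(rep)
  expect_true(is.na(df$calculated_mass[df$peak_mz == 500]))
})
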