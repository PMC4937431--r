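test_that("law verification is a pure function with sensible margins", {
  ix <- computeIndexes(generateRandomGenome(1e5, seed = 51))
  r1 <- verifyLaws(ix); r2 <- verifyLaws(ix)
  expect_identical(r1@laws, r2@laws)
  expect_true(r1@overall)
  expect_equal(r1@laws$law, c("L1", "L2", "L3", "L4", "L5"))
  expect_true(all(is.finite(r1@laws$margin)))
  expect_equal(r1@overall, all(r1@laws$pass))

  # hand-built boundary violation: E_2LG = 2LG makes L1 fail with margin 0
  bad <- ix
  bad@e2lg <- bad@twoLG
  bad@ec <- bad@e2lg - bad@lg
  bad@ac <- bad@twoLG - bad@e2lg
  bad@af <- bad@ac / bad@lg
  bad@eh <- 1 - 2 * bad@af
  rep <- verifyLaws(bad)
  expect_false(rep@laws$pass[rep@laws$law == "L1"])
  expect_equal(rep@laws$margin[rep@laws$law == "L1"], 0)
  expect_false(rep@overall)

  # super-ordered genome: L3 fails (AF >= 1/2), failures are data not errors
  sup <- verifyLaws(computeIndexes(makeFixture("periodic", n = 2^15)))
  expect_false(sup@laws$pass[sup@laws$law == "L3"])
  expect_true(sup@laws$pass[sup@laws$law == "L5"])  # theorem holds regardless

  # user-registered law predicates join the report
  extra <- list(Lbb = function(ix) list(pass = ix@bb > 0, lhs = ix@bb,
                                        rhs = 0, margin = ix@bb))
  rx <- verifyLaws(ix, extraLaws = extra)
  expect_true("Lbb" %in% rx@laws$law)

  js <- jsonlite::fromJSON(lawReportJSON(r1))
  expect_true(js$overall)
  expect_equal(nrow(js$laws), 5)
})

test_that("edit plans validate and apply in original coordinates", {
  g <- GenomeSequence("ACGTACGTACGT")

  del <- applyEdits(g, editPlan("delete", 0, 4))
  expect_equal(genomeRuns(del), "acgtacgt")

  # delete 10%: length bookkeeping is exact
  g2 <- generateRandomGenome(1000, seed = 2)
  d2 <- applyEdits(g2, editPlan("delete", 100, 100))
  expect_equal(effectiveLength(d2), 900)
  expect_equal(substr(genomeRuns(d2), 1, 100),
               substr(genomeRuns(g2), 1, 100))
  expect_equal(substr(genomeRuns(d2), 101, 900),
               substr(genomeRuns(g2), 201, 1000))

  # whole-genome shuffle: permutation conserves composition and length
  sh <- applyEdits(g2, editPlan("shuffle", 0, 1000, seed = 4))
  expect_equal(effectiveLength(sh), 1000)
  expect_equal(table(strsplit(genomeRuns(sh), "")[[1]]),
               table(strsplit(genomeRuns(g2), "")[[1]]))
  expect_false(identical(genomeRuns(sh), genomeRuns(g2)))
  # shuffle is deterministic in the plan seed
  expect_identical(
    genomeRuns(applyEdits(g2, editPlan("shuffle", 0, 1000, seed = 4))),
    genomeRuns(sh))

  # edits spanning run boundaries preserve the remaining structure
  gm <- GenomeSequence(c("AAAA", "CCCC"))
  dm <- applyEdits(gm, editPlan("delete", 2, 4))
  expect_equal(genomeRuns(dm), c("aa", "cc"))

  expect_error(applyEdits(g, editPlan("delete", 10, 5)), "bounds")
  expect_error(applyEdits(g, editPlan("delete", 0, 12)), "entire genome")
  expect_error(editPlan(c("delete", "shuffle"), c(0, 2), c(4, 4)),
               "overlap")
  expect_error(editPlan("invert", 0, 4), "kind")
})

test_that("law-survival scan records per-plan indexes and failures", {
  g <- makeFixture("block-mixture", n = 2e4, seed = 31,
                   orderedFraction = 0.25)
  plans <- list(
    identity = editPlan(),
    delOrdered = editPlan("delete", 0, 4000),
    shuffleAll = editPlan("shuffle", 0, 2e4, seed = 8),
    killAll = editPlan("delete", 0, 2e4))
  scan <- lawSurvivalScan(g, plans)
  expect_equal(scan$plan, names(plans))

  # identity row reproduces the unedited genome's indexes
  ix <- computeIndexes(g)
  expect_equal(scan$AC[1], ix@ac)
  expect_equal(scan$BB[1], ix@bb)
  expect_equal(scan$n[1], 2e4)

  # deleting the ordered block removes anti-entropy
  expect_lt(scan$AC[2], scan$AC[1])

  # whole-genome shuffle collapses AC to the random level at the same n
  ref <- computeIndexes(generateRandomGenome(2e4, seed = 77))
  expect_lt(scan$AC[3], 3 * max(ref@ac, randomEntropyGapBound(2e4)))
  expect_true(all(unlist(scan[3, c("L1", "L2", "L3", "L4", "L5")])))

  # degenerate plan is reported, scan continues
  expect_true(is.na(scan$n[4]))
  expect_match(scan$error[4], "entire genome")
  expect_true(all(is.na(scan[4, c("L1", "L2", "L3")])))
})

test_that("edit plans round-trip through JSON", {
  plans <- list(a = editPlan(c("delete", "shuffle"), c(0, 100), c(10, 20),
                             seed = 5),
                b = editPlan())
  path <- withr::local_tempfile(fileext = ".json")
  writeEditPlans(plans, path)
  back <- readEditPlans(path)
  expect_equal(names(back), c("a", "b"))
  expect_equal(back$a@ops, plans$a@ops)
  expect_equal(back$a@seed, 5L)
  expect_equal(nrow(back$b@ops), 0L)
})
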