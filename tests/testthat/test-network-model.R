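test_that("stoichiometric matrix of a linear chain has the forced form", {
  net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] -> B[c]",
                                R3 = "B[c] ->"))
  S <- buildStoichiometricMatrix(net)
  expect_identical(dim(S), c(2L, 3L))
  expect_identical(rownames(S), c("A[c]", "B[c]"))
  expect_equal(unname(S),
               matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE))
})

test_that("external species are excluded so exchange columns are unbalanced", {
  net <- networkFromEquations(c(Ex = "glc[e] -> glc[c]", R = "glc[c] ->"))
  S <- buildStoichiometricMatrix(net)
  expect_identical(rownames(S), "glc[c]")
  expect_equal(sum(S[, "Ex"]), 1)      # single-sided after dropping boundary row
  expect_identical(reactions(net)$kind[1], "exchange")
})

test_that("network -> matrix preserves every coefficient exactly", {
  for (seed in 1:20) {
    net <- makeRandomNetwork(seed, nMetabolites = 5, nReactions = 7)
    S <- buildStoichiometricMatrix(net, warnOrphans = FALSE)
    full <- as.matrix(stoichMatrix(net))
    expect_identical(S, full[rownames(S), , drop = FALSE])
    # rebuild a network from the matrix and compare coefficients
    net2 <- StoichiometricNetwork(metabolites(net), reactions(net),
                                  stoichMatrix(net), roles(net))
    expect_identical(as.matrix(stoichMatrix(net2)), full)
  }
})

test_that("a metabolite in no reaction yields a zero row and a warning", {
  net <- StoichiometricNetwork(
    metabolites = data.frame(id = c("A", "B", "lost"), compartment = "cytosol"),
    reactions = data.frame(id = c("R1", "R2")),
    stoichiometry = list(R1 = c(A = 1), R2 = c(A = -1, B = 1))
  )
  expect_warning(S <- buildStoichiometricMatrix(net), "lost")
  expect_equal(unname(S["lost", ]), c(0, 0))
  rep <- validateNetwork(net)
  expect_true("orphan_metabolite" %in% rep$code)
})

test_that("a reaction naming an unknown metabolite is a structural error", {
  expect_error(
    StoichiometricNetwork(
      metabolites = data.frame(id = "A", compartment = "cytosol"),
      reactions = data.frame(id = "Rbad"),
      stoichiometry = list(Rbad = c(A = -1, ghost = 1))
    ),
    "Rbad.*ghost"
  )
})

test_that("default bounds are 0..100 irreversible and -100..100 reversible", {
  net <- networkFromEquations(c(R1 = "A[c] -> B[c]", R2 = "B[c] <=> A[c]",
                                Ex = "-> A[c]"))
  net <- applyBounds(net)
  b <- bounds(net)
  rownames(b) <- reactions(net)$id
  expect_equal(b["R1", ], c(lower = 0, upper = 100))
  expect_equal(b["R2", ], c(lower = -100, upper = 100))
  expect_equal(b["Ex", ], c(lower = 0, upper = 100))
})

test_that("overrides replace defaults and express fixed fluxes as lb == ub", {
  net <- networkFromEquations(c(Ex = "-> atp[c]", R192 = "atp[c] ->"))
  net <- applyBounds(net, overrides = list(R192 = c(0.92, 0.92)))
  b <- bounds(net)
  i <- match("R192", reactions(net)$id)
  expect_identical(unname(b[i, ]), c(0.92, 0.92))
  expect_error(applyBounds(net, overrides = list(R192 = c(1, 0.5))),
               "lb <= ub")
  expect_error(applyBounds(net, overrides = list(nope = c(0, 1))), "nope")
})

test_that("applyBounds is idempotent", {
  net <- makeRandomNetwork(3, 6, 9, pReversible = 0.5)
  ov <- list(R01 = c(0.92, 0.92))
  once <- applyBounds(net, overrides = ov)
  twice <- applyBounds(once, overrides = ov)
  expect_identical(bounds(once), bounds(twice))
})

test_that("validation reports duplicates, missing roles and bound errors", {
  net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] ->"))
  expect_identical(nrow(validateNetwork(net)), 0L)   # clean toy: empty report

  rep <- validateNetwork(net, requireRoles = "biomass")
  expect_identical(rep$code, "role_absent")
  expect_match(rep$message, "named role absent")
  expect_identical(rep$severity, "warning")

  # force a duplicated reaction id past the constructor
  dup <- net
  r <- dup@reactions
  r$id[2] <- "R1"
  slot(dup, "reactions", check = FALSE) <- r
  rep <- validateNetwork(dup)
  expect_true("duplicate_reaction_id" %in% rep$code)
  expect_true("R1" %in% rep$subject)

  bad <- net
  r <- bad@reactions
  r$lower_bound <- c(5, 5)
  r$upper_bound <- c(1, 10)
  slot(bad, "reactions", check = FALSE) <- r
  rep <- validateNetwork(bad)
  expect_true("bound_order" %in% rep$code)
})

test_that("the network container enforces its invariants at construction", {
  expect_error(StoichiometricNetwork(
    metabolites = data.frame(id = "A", compartment = "vacuole"),
    reactions = data.frame(id = "R"), stoichiometry = list(R = c(A = 1))),
    "compartment")
  expect_error(StoichiometricNetwork(
    metabolites = data.frame(id = "A", compartment = "cytosol"),
    reactions = data.frame(id = "R", lower_bound = 2, upper_bound = 1),
    stoichiometry = list(R = c(A = 1))),
    "lower_bound")
  expect_error(StoichiometricNetwork(
    metabolites = data.frame(id = "A", compartment = "cytosol"),
    reactions = data.frame(id = "R"), stoichiometry = list(R = c(A = 1)),
    roles = c(biomass = "missing")),
    "unknown reaction")
})
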