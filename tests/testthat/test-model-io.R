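test_that("equation parsing handles coefficients, compartments and arrows", {
  p <- parseReactionEquation("glc[c] + 2 atp[c] -> g6p[c] + 2 adp[c]")
  expect_false(p$reversible)
  expect_equal(p$stoichiometry,
               c(`glc[c]` = -1, `atp[c]` = -2, `g6p[c]` = 1, `adp[c]` = 2))

  p <- parseReactionEquation("dhap[h] <=> dhap[c]")
  expect_true(p$reversible)
  expect_equal(p$stoichiometry, c(`dhap[h]` = -1, `dhap[c]` = 1))

  p <- parseReactionEquation("-> co2[e]")        # exchange, empty left side
  expect_equal(p$stoichiometry, c(`co2[e]` = 1))

  p <- parseReactionEquation("0.5 o2[c] + 3/2 nadh[c] -> 3/2 nad[c]")
  expect_equal(unname(p$stoichiometry), c(-0.5, -1.5, 1.5))
})

test_that("equation parse errors carry a character position", {
  expect_error(parseReactionEquation("A[c] + B[c]"), "no reaction arrow")
  expect_error(parseReactionEquation("A[c] + -> B[c]"),
               "position \\d+: empty term")
  expect_error(parseReactionEquation("2..5 atp[c] -> adp[c]"),
               "non-numeric coefficient")
})

test_that("format then parse is the identity on canonical equations", {
  eqs <- c("glc[c] + 2 atp[c] -> g6p[c] + 2 adp[c]",
           "dhap[h] <=> dhap[c]",
           "-> photon[h]",
           "5 n[c] + 50 atp[c] ->",
           "0.25 a[m] + 1.5 b[m] -> c[m]")
  for (eq in eqs) {
    p <- parseReactionEquation(eq)
    q <- parseReactionEquation(formatReactionEquation(p$stoichiometry,
                                                      p$reversible))
    expect_equal(q$stoichiometry, p$stoichiometry)
    expect_identical(q$reversible, p$reversible)
  }
})

expectNetworksIdentical <- function(a, b) {
  expect_identical(as.data.frame(metabolites(a)), as.data.frame(metabolites(b)))
  expect_identical(as.data.frame(reactions(a)), as.data.frame(reactions(b)))
  expect_identical(as.matrix(stoichMatrix(a)), as.matrix(stoichMatrix(b)))
  expect_identical(roles(a), roles(b))
}

test_that("SBML write/read round-trips the toy phototroph exactly", {
  toy <- makeToyPhototroph()
  f <- withr::local_tempfile(fileext = ".xml")
  writeSBML(toy$network, f)
  expectNetworksIdentical(readSBML(f), toy$network)
})

test_that("SBML output is deterministic and bounds round-trip exactly", {
  net <- networkFromEquations(c(Ex = "-> atp[c]", R192 = "atp[c] ->"))
  net <- applyBounds(net, overrides = list(R192 = c(0.92, 0.92)))
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeSBML(net, f1)
  writeSBML(net, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- readSBML(f1)
  i <- match("R192", reactions(back)$id)
  expect_identical(unname(bounds(back)[i, ]), c(0.92, 0.92))
})

test_that("SBML round-trip identity holds over random networks", {
  for (seed in 1:25) {
    net <- makeRandomNetwork(seed, nMetabolites = 3 + seed %% 5,
                             nReactions = 4 + seed %% 7,
                             pReversible = (seed %% 4) / 4)
    f <- tempfile(fileext = ".xml")
    writeSBML(net, f)
    expectNetworksIdentical(readSBML(f), net)
    file.remove(f)
  }
})

test_that("reading the same SBML file twice gives identical networks", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeSBML(makeRandomNetwork(11, 5, 7), f)
  expectNetworksIdentical(readSBML(f), readSBML(f))
})

test_that("legacy kineticLaw bounds and boundary species are accepted", {
  legacy <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m">',
    '    <listOfCompartments><compartment id="cyt"/><compartment id="ext"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A" compartment="cyt"/>',
    '      <species id="Ab" compartment="ext" boundaryCondition="true"/>',
    '    </listOfSpecies>',
    '    <listOfReactions>',
    '      <reaction id="Ex" reversible="false">',
    '        <listOfReactants><speciesReference species="Ab"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="A"/></listOfProducts>',
    '        <kineticLaw><listOfParameters>',
    '          <parameter id="LOWER_BOUND" value="0"/>',
    '          <parameter id="UPPER_BOUND" value="5"/>',
    '        </listOfParameters></kineticLaw>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(legacy, f)
  net <- readSBML(f)
  expect_identical(metabolites(net)$compartment,
                   c("cytosol", "external"))
  i <- match("Ex", reactions(net)$id)
  expect_identical(unname(bounds(net)[i, ]), c(0, 5))
  expect_identical(reactions(net)$kind[i], "exchange")   # boundary-species dialect
  # the boundary row is dropped from S, so the column is single-sided
  expect_equal(unname(buildStoichiometricMatrix(net)["A", "Ex"]), 1)
})

test_that("SBML referencing a missing compartment names the species", {
  bad <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m">',
    '    <listOfCompartments><compartment id="cyt"/></listOfCompartments>',
    '    <listOfSpecies><species id="A" compartment="nowhere"/></listOfSpecies>',
    '  </model>',
    '</sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(bad, f)
  expect_error(readSBML(f), "unknown compartment|missing compartment")
  expect_error(readSBML(withr::local_tempfile(fileext = ".xml")), "no such file")
})

test_that("reaction tables read with delimiter sniffing and NA annotations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,equation,ec,kegg",
               "Ex01,-> glc[c],,",
               "Eno,2pg[c] <=> pep[c],4.2.1.11,R00658",
               "R2,glc[c] ->,,"), f)
  rows <- readReactionTable(f)
  expect_identical(nrow(rows), 3L)
  expect_identical(rows$ec_number, c(NA, "4.2.1.11", NA))
  expect_identical(rows$kegg_id, c(NA, "R00658", NA))
  net <- reactionTableToNetwork(rows)
  expect_identical(nrow(reactions(net)), 3L)
  expect_identical(reactions(net)$ec_number[2], "4.2.1.11")

  ftsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tequation", "R1\t-> A[c]"), ftsv)
  expect_identical(nrow(readReactionTable(ftsv)), 1L)
})

test_that("a reaction table lacking mandatory columns is a schema error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,name", "R1,foo"), f)
  expect_error(readReactionTable(f), "equation")
})

test_that("scenario tables round-trip through the two-way layout", {
  toy <- makeToyPhototroph()
  tab <- runScenarios(toy$network, c("A", "B", "C", "D"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeScenarioTable(tab, f)
  lines <- readLines(f)
  expect_identical(length(lines), 7L)          # header + 6 quantity rows
  back <- readScenarioTable(f)
  expect_identical(back$label, tab$label)
  expect_equal(back$growth_rate, round(tab$growth_rate, 4))
  expect_equal(back$Ex01, tab$Ex01)
  # growth-rate row has one entry per scenario
  expect_identical(sum(!is.na(back$growth_rate)), 4L)
})

test_that("an empty scenario table writes a header-only layout", {
  toy <- makeToyPhototroph()
  tab <- runScenarios(toy$network, character(0))
  f <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(label = character(), Ex01 = numeric(),
                      Ex06 = numeric(), objective = character(),
                      growth_rate = numeric(), carotene_flux = numeric(),
                      status = character())
  writeScenarioTable(empty, f)
  expect_identical(length(readLines(f)), 7L)   # quantity column only
  expect_null(tab)
})
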