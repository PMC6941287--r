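test_that("a capped linear chain maximises at the uptake bound", {
  net <- makeChain(cap = 5)
  res <- solveFBA(net, c(R3 = 1))
  expect_optimal(res)
  expect_equal(res@stageValues, 5, tolerance = 1e-9)
  expect_equal(unname(res@flux), c(5, 5, 5), tolerance = 1e-9)
})

test_that("all-zero bounds force a zero optimum and zero fluxes", {
  net <- makeChain()
  ids <- reactions(net)$id
  ov <- stats::setNames(rep(list(c(0, 0)), length(ids)), ids)
  net <- applyBounds(net, overrides = ov)
  res <- solveFBA(net, c(R3 = 1))
  expect_optimal(res)
  expect_equal(res@stageValues, 0)
  expect_equal(max(abs(res@flux)), 0)
})

test_that("an uncapped objective is reported unbounded with its support", {
  net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] ->"))
  net <- applyBounds(net, overrides = list(R1 = c(0, Inf), R2 = c(0, Inf)))
  res <- solveFBA(net, c(R2 = 1))
  expect_identical(res@status, "unbounded")
  expect_setequal(res@unboundedSupport, c("R1", "R2"))
})

test_that("an infeasible scenario is reported as such, not as an error", {
  net <- applyBounds(makeChain(cap = 5), overrides = list(R3 = c(10, 10)))
  expect_identical(solveFBA(net, c(R3 = 1))@status, "infeasible")
})

test_that("LP optimum equals the vertex-enumeration oracle on random networks", {
  nAgree <- 0L
  for (seed in 1:40) {
    net <- makeRandomNetwork(seed, nMetabolites = 3 + seed %% 5,
                             nReactions = 5 + seed %% 5,
                             pReversible = (seed %% 3) / 3)
    cc <- randomObjective(net, seed)
    lp <- solveFBA(net, cc)
    or <- enumerateVerticesOracle(net, cc)
    expect_optimal(lp)
    expect_identical(or$status, "optimal")
    expect_equal(lp@stageValues, or$obj,
                 tolerance = 1e-6 / max(1, abs(or$obj)))
    nAgree <- nAgree + 1L
  }
  expect_identical(nAgree, 40L)
})

test_that("oracle and LP agree that forced contradictions are infeasible", {
  net <- applyBounds(makeChain(cap = 5), overrides = list(R3 = c(10, 10)))
  expect_identical(enumerateVerticesOracle(net, c(R3 = 1))$status, "infeasible")
  expect_identical(solveFBA(net, c(R3 = 1))@status, "infeasible")
})

test_that("the oracle refuses instances beyond its size limit", {
  net <- makeRandomNetwork(1, 8, 13)
  expect_error(enumerateVerticesOracle(net, randomObjective(net, 1)),
               "refus")
})

test_that("optimal fluxes satisfy steady state and bounds", {
  for (seed in 1:25) {
    net <- makeRandomNetwork(seed, nMetabolites = 4 + seed %% 5,
                             nReactions = 6 + seed %% 7,
                             pReversible = 0.4)
    res <- solveFBA(net, randomObjective(net, seed))
    expect_optimal(res)
    expect_lte(steadyStateResidual(net, res@flux), 1e-6)
    expect_lte(boundViolation(net, res@flux), 1e-9)
    # the reported stage value is the inner product on the returned vertex
    cc <- randomObjective(net, seed)
    expect_equal(sum(cc * res@flux[names(cc)]), res@stageValues,
                 tolerance = 1e-6)
  }
})

test_that("enlarging any bound interval never decreases the optimum", {
  for (seed in 1:15) {
    net <- makeRandomNetwork(seed, 5, 8, pReversible = 0.3)
    cc <- randomObjective(net, seed)
    base <- solveFBA(net, cc)@stageValues
    ids <- reactions(net)$id
    j <- ids[(seed %% length(ids)) + 1]
    b <- bounds(net)[match(j, ids), ]
    wide <- applyBounds(net, overrides = stats::setNames(
      list(c(b[["lower"]] - 7, b[["upper"]] + 7)), j))
    expect_gte(solveFBA(wide, cc)@stageValues, base - 1e-9)
  }
})

test_that("scaling all bounds by lambda scales every stage optimum by lambda", {
  toy <- makeToyPhototroph()
  obj <- objectiveSpec(c(biomass = 1), c(carotene_sink = 1))
  base <- solveLexicographic(toy$network, obj)
  for (lambda in c(0.5, 2, 3.7)) {
    net <- toy$network
    rxn <- reactions(net)
    ov <- lapply(seq_len(nrow(rxn)), function(i) {
      lambda * c(rxn$lower_bound[i], rxn$upper_bound[i])
    })
    names(ov) <- rxn$id
    scaled <- applyBounds(net, overrides = ov)
    res <- solveLexicographic(scaled, obj)
    expect_equal(res@stageValues, lambda * base@stageValues,
                 tolerance = 1e-8)
  }
})

test_that("lexicographic stage 1 equals the single-objective optimum", {
  toy <- makeToyPhototroph()
  single <- solveFBA(toy$network, c(biomass = 1))
  lex <- solveLexicographic(toy$network,
                            objectiveSpec(c(biomass = 1), c(carotene_sink = 1)))
  expect_equal(lex@stageValues[1], single@stageValues, tolerance = 1e-6)
  expect_equal(lex@mu, single@mu, tolerance = 1e-6)
})

test_that("independent branches reach their standalone maxima under staging", {
  # two uptakes feeding two separate sinks: the stages do not compete
  net <- networkFromEquations(c(U1 = "-> a[c]", S1 = "a[c] ->",
                                U2 = "-> b[c]", S2 = "b[c] ->"))
  net <- applyBounds(net, overrides = list(U1 = c(0, 3), U2 = c(0, 7)))
  lex <- solveLexicographic(net, objectiveSpec(c(S1 = 1), c(S2 = 1)))
  expect_equal(lex@stageValues, c(3, 7), tolerance = 1e-9)
})

test_that("competing stages: stage 2 receives exactly the leftover capacity", {
  # one uptake (cap 10) feeds both sinks; stage 1 takes it all, so a direct
  # stage-2 claim must be zero; with stage 1 demanded at most 4 (ub), 6 remain
  net <- networkFromEquations(c(U = "-> a[c]", S1 = "a[c] ->", S2 = "a[c] ->"))
  net <- applyBounds(net, overrides = list(U = c(0, 10)))
  lex <- solveLexicographic(net, objectiveSpec(c(S1 = 1), c(S2 = 1)))
  expect_equal(lex@stageValues, c(10, 0), tolerance = 1e-9)

  capped <- applyBounds(net, overrides = list(S1 = c(0, 4)))
  lex <- solveLexicographic(capped, objectiveSpec(c(S1 = 1), c(S2 = 1)))
  expect_equal(lex@stageValues, c(4, 6), tolerance = 1e-9)
  # the stage-2 LP (stage 1 anchored at 4) agrees with the vertex oracle
  anchored <- applyBounds(capped, overrides = list(S1 = c(4, 4)))
  or <- enumerateVerticesOracle(anchored, c(S2 = 1))
  expect_equal(lex@stageValues[2], or$obj, tolerance = 1e-6)
})

test_that("weighted-sum mode is available and differs from staging", {
  net <- networkFromEquations(c(U = "-> a[c]", S1 = "a[c] ->", S2 = "a[c] ->"))
  net <- applyBounds(net, overrides = list(U = c(0, 10)))
  res <- solveLexicographic(net, objectiveSpec(c(S1 = 1), c(S2 = 1)),
                            mode = "weighted", weights = c(1, 2))
  expect_optimal(res)
  expect_equal(sum(res@stageValues), 10, tolerance = 1e-9)
  expect_equal(res@stageValues[2], 10, tolerance = 1e-9)  # heavier stage wins
})

test_that("the l1 tie-break returns a minimal-total-flux optimal vertex", {
  # a futile reversible cycle admits many optimal vertices; the l1 polish
  # must drive the cycle flux to zero without changing the objective
  net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] -> B[c]",
                                Rcyc = "B[c] <=> A[c]", R3 = "B[c] ->"))
  net <- applyBounds(net, overrides = list(R1 = c(0, 5)))
  res <- solveFBA(net, c(R3 = 1), tieBreak = "l1")
  expect_equal(res@stageValues, 5, tolerance = 1e-9)
  # minimal total flux is 15 (5 through each chain step, no futile cycling);
  # without the polish the cycle may carry up to 100 extra units
  expect_equal(sum(abs(res@flux)), 15, tolerance = 1e-8)
})

test_that("the LP engine matches an external interior-point/simplex solver", {
  # independent cross-check through scipy's HiGHS backend on a fixed panel
  inst <- list()
  for (seed in c(3, 9, 17, 23, 31, 41)) {
    net <- makeRandomNetwork(seed, nMetabolites = 4 + seed %% 4,
                             nReactions = 6 + seed %% 6, pReversible = 0.4)
    cc <- randomObjective(net, seed)
    S <- buildStoichiometricMatrix(net, warnOrphans = FALSE)
    b <- bounds(net)
    inst[[length(inst) + 1]] <- list(
      S = as.vector(t(S)), m = nrow(S), n = ncol(S),
      lb = unname(b[, "lower"]), ub = unname(b[, "upper"]),
      c = unname(cc), ours = solveFBA(net, cc)@stageValues)
  }
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(inst, fin, digits = NA, auto_unbox = TRUE)
  code <- paste(
    "import json,sys,numpy as np",
    "from scipy.optimize import linprog",
    sprintf("inst=json.load(open('%s'))", fin),
    "out=[]",
    "for k in inst:",
    "    S=np.array(k['S']).reshape(k['m'],k['n'])",
    "    r=linprog([-x for x in k['c']],A_eq=S,b_eq=np.zeros(k['m']),",
    "              bounds=list(zip(k['lb'],k['ub'])),method='highs')",
    "    out.append(-r.fun if r.status==0 else None)",
    sprintf("json.dump(out,open('%s','w'))", fout),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)
  ref <- unlist(jsonlite::read_json(fout))
  ours <- vapply(inst, `[[`, numeric(1), "ours")
  expect_equal(ours, ref, tolerance = 1e-6)
  file.remove(fin, fout)
})
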