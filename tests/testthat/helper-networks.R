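# Shared fixtures, built in code.

# linear chain: uptake -> A -> B -> secretion, with an uptake cap
makeChain <- function(cap = 5) {
  net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] -> B[c]",
                                R3 = "B[c] ->"))
  applyBounds(net, overrides = list(R1 = c(0, cap)))
}

# random single-stage objective over a network's reactions
randomObjective <- function(net, seed) {
  n <- nrow(reactions(net))
  w <- sin(seed + seq_len(n))          # deterministic, seed-dependent
  stats::setNames(w, reactions(net)$id)
}

# steady-state residual of a flux vector on a network
steadyStateResidual <- function(net, flux) {
  S <- buildStoichiometricMatrix(net, warnOrphans = FALSE)
  if (!nrow(S)) return(0)
  max(abs(S %*% flux[colnames(S)]))
}

# largest bound violation of a flux vector
boundViolation <- function(net, flux) {
  b <- bounds(net)
  v <- flux[reactions(net)$id]
  max(c(b[, "lower"] - v, v - b[, "upper"], 0))
}

expect_optimal <- function(res) {
  expect_s4_class(res, "FBAResult")
  expect_identical(res@status, "optimal")
}
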