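# Synthetic networks with known optima.
#
# The toy phototroph is a three-compartment skeleton of photoautotrophic
# growth: photons are taken up into the chloroplast and converted to a
# generic energy currency (y_E energy units per photon); nitrate is taken
# up and assimilated in the cytosol; biomass formation drains n_N mmol
# nitrogen and n_E energy units per g dry weight; a fixed maintenance drain
# m_ATP runs in the mitochondrion; and a secondary-pigment branch spends
# k_car energy units per mmol beta-carotene exported through a sink. Its
# optima have closed forms:
#
#   mu*   = min( v_N_max / n_N , (y_E v_light_max - m_ATP) / n_E )
#   Car*  = max( 0, (y_E v_light_max - m_ATP - n_E mu*) / k_car )
#
# so the LP engine, the lexicographic staging and the scenario runner can
# all be verified against arithmetic.

#' Parameters of the toy phototroph
#'
#' Defaults mirror the low-light, nutrient-replete study condition
#' (photon cap 320, nitrate cap 0.19, maintenance 0.92 mmol/(g dw h)) with
#' field-realistic composition values: `nN` = 5 mmol nitrogen per g dw
#' (about 7 percent nitrogen by weight), `nE` = 50 mmol energy units per
#' g dw, `yE` = 0.125 energy units per photon (order of the photosynthetic
#' quantum requirement), `kCar` = 20 energy units per mmol beta-carotene.
#'
#' @param nN mmol nitrate per g dw biomass (> 0).
#' @param nE mmol energy units per g dw biomass (> 0).
#' @param yE energy units per photon (> 0).
#' @param mATP maintenance drain, mmol/(g dw h) (> 0).
#' @param kCar energy units per mmol carotene (> 0).
#' @param vLightMax,vNMax uptake caps, mmol/(g dw h) (> 0).
#' @return list of class `PhototrophParams`
#' @export
phototrophParams <- function(nN = 5, nE = 50, yE = 0.125, mATP = 0.92,
                             kCar = 20, vLightMax = 320, vNMax = 0.19) {
  p <- list(nN = nN, nE = nE, yE = yE, mATP = mATP, kCar = kCar,
            vLightMax = vLightMax, vNMax = vNMax)
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("phototroph parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  }
  structure(p, class = "PhototrophParams")
}

#' Closed-form optima of the toy phototroph
#'
#' @param params a [phototrophParams()] object.
#' @return named numeric: `mu` (growth at max-growth optimum, 1/h) and
#'   `car` (carotene flux at the growth-anchored second stage,
#'   mmol/(g dw h)). Both `NA` when the light supply cannot cover the
#'   maintenance drain (the scenario is infeasible).
#' @export
phototrophOptima <- function(params) {
  stopifnot(inherits(params, "PhototrophParams"))
  eTot <- params$yE * params$vLightMax
  if (eTot < params$mATP) return(c(mu = NA_real_, car = NA_real_))
  mu <- min(params$vNMax / params$nN, (eTot - params$mATP) / params$nE)
  car <- max(0, (eTot - params$mATP - params$nE * mu) / params$kCar)
  c(mu = mu, car = car)
}

#' Build the toy phototroph network
#'
#' Three compartments (chloroplast `h`, cytosol `c`, mitochondrion `m`),
#' ten reactions, with the five canonical roles named: photon exchange
#' `Ex01`, nitrate exchange `Ex06`, maintenance `R192` (bounds fixed at
#' `mATP`), biomass `mu`, carotene sink `Car14`. Uptake caps are baked into
#' the exchange bounds, so the returned network is solvable as-is;
#' a [FluxScenario-class] can still re-drive the roles.
#'
#' @param params a [phototrophParams()] object.
#' @return list with `network` (a [StoichiometricNetwork-class]), `params`,
#'   and `optima` (the closed forms from [phototrophOptima()]).
#' @examples
#' toy <- makeToyPhototroph()
#' solveFBA(toy$network, c(biomass = 1))@mu   # equals toy$optima[["mu"]]
#' @export
makeToyPhototroph <- function(params = phototrophParams()) {
  stopifnot(inherits(params, "PhototrophParams"))
  eq <- c(
    Ex01 = "-> photon_h",
    Ex06 = "-> no3_c",
    R01 = sprintf("photon_h -> %.17g atp_h", params$yE),
    T01 = "atp_h <=> atp_c",
    R02 = "no3_c -> norg_c",
    T02 = "atp_c -> atp_m",
    R192 = "atp_m ->",
    Rcar = sprintf("%.17g atp_h -> car_h", params$kCar),
    Car14 = "car_h ->",
    mu = sprintf("%.17g norg_c + %.17g atp_c ->", params$nN, params$nE)
  )
  net <- networkFromEquations(
    eq,
    kind = c("exchange", "exchange", "internal", "transport", "internal",
             "transport", "maintenance", "internal", "exchange", "biomass"),
    roles = c(biomass = "mu", light_exchange = "Ex01",
              nitrate_exchange = "Ex06", maintenance = "R192",
              carotene_sink = "Car14")
  )
  comp <- c(photon_h = "chloroplast", atp_h = "chloroplast",
            car_h = "chloroplast", no3_c = "cytosol", norg_c = "cytosol",
            atp_c = "cytosol", atp_m = "mitochondrion")
  net@metabolites$compartment <- unname(comp[net@metabolites$id])
  # internal machinery gets explicit wide capacity (1e4) so that only the
  # uptake caps and the maintenance drain can bind -- the assumption behind
  # the closed forms
  wide <- 1e4
  net <- applyBounds(net, overrides = list(
    Ex01 = c(0, params$vLightMax),
    Ex06 = c(0, params$vNMax),
    R192 = c(params$mATP, params$mATP),
    R01 = c(0, wide), T01 = c(-wide, wide), R02 = c(0, wide),
    T02 = c(0, wide), Rcar = c(0, wide), Car14 = c(0, wide),
    mu = c(0, wide)
  ))
  list(network = net, params = params, optima = phototrophOptima(params))
}

# run fn with a private RNG stream; the global seed state is untouched
.withSeed <- function(seed, fn) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Generate a random sparse stoichiometric network
#'
#' Reproducible (the seed is an explicit argument; global RNG state is
#' untouched), always feasible (every bound interval contains zero, so the
#' zero flux is a steady state), with small-integer coefficients in
#' {-2, -1, 1, 2} so vertex enumeration stays well conditioned. About one
#' reaction in five is an unbalanced single-species exchange column, and
#' each reaction is reversible with probability `pReversible`. Default
#' bounds are applied (0..100 irreversible, -100..100 reversible).
#'
#' @param seed integer seed.
#' @param nMetabolites,nReactions network size (>= 1).
#' @param pReversible probability a reaction is reversible, in 0..1.
#' @return a [StoichiometricNetwork-class]
#' @examples
#' net <- makeRandomNetwork(42, nMetabolites = 5, nReactions = 8)
#' checkFeasibility(net)$feasible   # TRUE by construction
#' @export
makeRandomNetwork <- function(seed, nMetabolites = 6, nReactions = 8,
                              pReversible = 0.3) {
  stopifnot(nMetabolites >= 1, nReactions >= 1,
            pReversible >= 0, pReversible <= 1)
  .withSeed(seed, function() {
    metIds <- sprintf("M%02d", seq_len(nMetabolites))
    rxnIds <- sprintf("R%02d", seq_len(nReactions))
    comp <- rep_len(c("cytosol", "chloroplast", "mitochondrion"), nMetabolites)
    coefPool <- c(-2, -1, 1, 2)
    stoich <- vector("list", nReactions)
    kinds <- character(nReactions)
    for (j in seq_len(nReactions)) {
      if (runif(1) < 0.2 || nMetabolites == 1L) {
        i <- sample.int(nMetabolites, 1L)
        stoich[[j]] <- stats::setNames(sample(c(-1, 1), 1L), metIds[i])
        kinds[j] <- "exchange"
      } else {
        k <- sample(2:min(3, nMetabolites), 1L)
        i <- sample.int(nMetabolites, k)
        co <- sample(coefPool, k, replace = TRUE)
        if (all(co > 0)) co[1] <- -co[1]   # keep at least one substrate
        if (all(co < 0)) co[1] <- -co[1]
        stoich[[j]] <- stats::setNames(co, metIds[i])
        kinds[j] <- "internal"
      }
    }
    # attach unused metabolites to an existing reaction so no orphans remain
    used <- unique(unlist(lapply(stoich, names)))
    for (id in setdiff(metIds, used)) {
      j <- sample.int(nReactions, 1L)
      stoich[[j]] <- c(stoich[[j]],
                       stats::setNames(sample(coefPool, 1L), id))
    }
    names(stoich) <- rxnIds
    net <- StoichiometricNetwork(
      metabolites = data.frame(id = metIds, compartment = comp),
      reactions = data.frame(id = rxnIds,
                             reversible = runif(nReactions) < pReversible,
                             kind = kinds),
      stoichiometry = stoich
    )
    applyBounds(net)
  })
}
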