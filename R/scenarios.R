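# Canonical light x nutrient scenarios and the scenario runner.
#
# The eight canonical scenarios cross two photon uptake rates (low light
# 320, high light 800 mmol/(g dw h)) with two nitrate uptake rates
# (replete 0.19, depleted 0.001 mmol/(g dw h)). A-D maximise growth alone;
# E-H maximise growth, then beta-carotene production at unchanged growth
# (lexicographic). The maintenance ATP drain is fixed at 0.92 mmol/(g dw h)
# throughout. Driven exchanges are capped (0..value) by default: the stated
# rates are maximal uptake rates, and under maximisation a binding cap
# coincides with an equality where the resource limits the objective.

.SCENARIO_GRID <- list(
  A = list(light = 320, nitrate = 0.19, staged = FALSE),
  B = list(light = 800, nitrate = 0.19, staged = FALSE),
  C = list(light = 320, nitrate = 0.001, staged = FALSE),
  D = list(light = 800, nitrate = 0.001, staged = FALSE),
  E = list(light = 320, nitrate = 0.19, staged = TRUE),
  F = list(light = 800, nitrate = 0.19, staged = TRUE),
  G = list(light = 320, nitrate = 0.001, staged = TRUE),
  H = list(light = 800, nitrate = 0.001, staged = TRUE)
)

#' Construct a canonical scenario
#'
#' @param label one of `"A"`..`"H"`.
#' @param boundMode bound mode for the two driven exchanges, `"capped"`
#'   (default; bounds 0..rate) or `"fixed"` (lb = ub = rate).
#' @param maintenanceFlux fixed maintenance ATP drain, default 0.92
#'   mmol/(g dw h).
#' @return a [FluxScenario-class]
#' @examples
#' makeScenario("A")   # low light, nutrient replete, max growth
#' makeScenario("H")   # high light, nutrient depleted, growth then carotene
#' @export
makeScenario <- function(label, boundMode = "capped", maintenanceFlux = 0.92) {
  if (length(label) != 1L || !label %in% names(.SCENARIO_GRID)) {
    stop("unknown scenario label '", label, "'; valid labels: ",
         paste(names(.SCENARIO_GRID), collapse = ", "))
  }
  g <- .SCENARIO_GRID[[label]]
  obj <- if (g$staged) {
    objectiveSpec(c(biomass = 1), c(carotene_sink = 1))
  } else {
    objectiveSpec(c(biomass = 1))
  }
  fluxScenario(label = label, objective = obj,
               lightFlux = g$light, nitrateFlux = g$nitrate,
               maintenanceFlux = maintenanceFlux,
               boundMode = c(light = boundMode, nitrate = boundMode))
}

#' Apply a scenario's bounds to a network
#'
#' Resolves the scenario's driven rates against the network's named roles
#' (light_exchange, nitrate_exchange, maintenance) and sets the
#' corresponding bounds: capped rates become `(0, rate)`, fixed rates and
#' the maintenance drain become `(rate, rate)`. Extra overrides are applied
#' last. Bounds not touched stay as they are ([applyBounds()] fills any
#' remaining `NA` with the defaults downstream).
#'
#' @param network a [StoichiometricNetwork-class].
#' @param scenario a [FluxScenario-class].
#' @return the network with scenario bounds set.
#' @export
applyScenario <- function(network, scenario) {
  stopifnot(is(network, "StoichiometricNetwork"), is(scenario, "FluxScenario"))
  roles <- network@roles
  ov <- list()
  setRole <- function(role, value, mode) {
    if (is.na(value)) return()
    if (!role %in% names(roles)) {
      stop(sprintf("scenario drives role '%s' but the network does not name it", role))
    }
    ov[[roles[[role]]]] <<- if (mode == "fixed") c(value, value) else c(0, value)
  }
  setRole("light_exchange", scenario@lightFlux, scenario@boundMode[["light"]])
  setRole("nitrate_exchange", scenario@nitrateFlux, scenario@boundMode[["nitrate"]])
  setRole("maintenance", scenario@maintenanceFlux, "fixed")
  ov[names(scenario@overrides)] <- scenario@overrides
  rxn <- network@reactions
  for (id in names(ov)) {
    i <- match(id, rxn$id)
    if (is.na(i)) stop("scenario override references unknown reaction: ", id)
    p <- as.numeric(ov[[id]])
    rxn$lower_bound[i] <- p[1]
    rxn$upper_bound[i] <- p[2]
    if (p[1] < 0) rxn$reversible[i] <- TRUE
  }
  network@reactions <- rxn
  validObject(network)
  network
}

.objectiveText <- function(spec) {
  nm <- unlist(lapply(spec@stages, function(s) names(s)))
  pretty <- c(biomass = "mu", carotene_sink = "Car14")
  nm <- ifelse(nm %in% names(pretty), pretty[nm], nm)
  paste0("max(", paste(nm, collapse = ","), ")")
}

#' Run a set of scenarios and tabulate the results
#'
#' Solves each scenario (plain FBA for single-stage objectives,
#' lexicographic FBA otherwise) and collects one row per scenario: the
#' input rates, the objective, the computed growth rate (1/h), the
#' beta-carotene flux (mmol/(g dw h)) and the solver status. Values are
#' stored at full precision; [writeScenarioTable()] rounds for display.
#' A failing scenario is recorded in its row's status and the run
#' continues.
#'
#' @param network a [StoichiometricNetwork-class] with the relevant roles.
#' @param scenarios character vector of canonical labels (default A-H)
#'   and/or a list of [FluxScenario-class] objects.
#' @param boundMode bound mode passed to [makeScenario()] for labels.
#' @return data.frame with columns `label`, `Ex01`, `Ex06`, `objective`,
#'   `growth_rate`, `carotene_flux`, `status`.
#' @examples
#' toy <- makeToyPhototroph()
#' runScenarios(toy$network, c("A", "E"))
#' @export
runScenarios <- function(network, scenarios = names(.SCENARIO_GRID),
                         boundMode = "capped") {
  if (is.character(scenarios)) {
    scenarios <- lapply(scenarios, makeScenario, boundMode = boundMode)
  }
  rows <- lapply(scenarios, function(sc) {
    stopifnot(is(sc, "FluxScenario"))
    k <- length(sc@objective@stages)
    res <- tryCatch({
      if (k == 1L) solveFBA(network, scenario = sc)
      else solveLexicographic(network, scenario = sc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(label = sc@label, Ex01 = sc@lightFlux,
                        Ex06 = sc@nitrateFlux,
                        objective = .objectiveText(sc@objective),
                        growth_rate = NA_real_, carotene_flux = NA_real_,
                        status = paste("error:", conditionMessage(res)),
                        stringsAsFactors = FALSE))
    }
    car <- if ("carotene_sink" %in% names(res@namedFluxes)) {
      unname(res@namedFluxes[["carotene_sink"]])
    } else NA_real_
    data.frame(label = sc@label, Ex01 = sc@lightFlux, Ex06 = sc@nitrateFlux,
               objective = .objectiveText(sc@objective),
               growth_rate = res@mu,
               carotene_flux = car,
               status = res@status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two scenario tables cell by cell
#'
#' Computes the relative deviation of every numeric cell (absolute
#' deviation where the reference cell is zero) between a computed and a
#' reference scenario table, matched by label, and reports the maximum and
#' a pass/fail verdict at `relTol`.
#'
#' @param computed,reference scenario tables ([runScenarios()] layout).
#' @param relTol relative tolerance, default 1e-3.
#' @return list with `perCell` (data.frame: label, quantity, computed,
#'   reference, deviation), `maxDeviation`, `pass`, `relTol`, and
#'   `failures` (rows exceeding the tolerance).
#' @export
compareScenarioTables <- function(computed, reference, relTol = 1e-3) {
  if (!setequal(computed$label, reference$label) ||
      anyDuplicated(computed$label) || anyDuplicated(reference$label)) {
    stop("scenario tables carry different label sets")
  }
  reference <- reference[match(computed$label, reference$label), ]
  quantities <- intersect(c("Ex01", "Ex06", "growth_rate", "carotene_flux"),
                          intersect(names(computed), names(reference)))
  cells <- list()
  for (q in quantities) {
    cv <- computed[[q]]; rv <- reference[[q]]
    use <- !is.na(cv) & !is.na(rv)
    dev <- abs(cv - rv) / ifelse(rv != 0, abs(rv), 1)
    cells[[q]] <- data.frame(label = computed$label[use], quantity = q,
                             computed = cv[use], reference = rv[use],
                             deviation = dev[use], stringsAsFactors = FALSE)
  }
  perCell <- do.call(rbind, c(cells, list(make.row.names = FALSE)))
  if (is.null(perCell)) {
    perCell <- data.frame(label = character(), quantity = character(),
                          computed = numeric(), reference = numeric(),
                          deviation = numeric())
  }
  maxDev <- if (nrow(perCell)) max(perCell$deviation) else 0
  failures <- perCell[perCell$deviation > relTol, , drop = FALSE]
  list(perCell = perCell, maxDeviation = maxDev,
       pass = nrow(failures) == 0L, relTol = relTol, failures = failures)
}
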