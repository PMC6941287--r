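#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Matrix dgCMatrix
NULL

.COMPARTMENTS <- c("cytosol", "chloroplast", "mitochondrion", "external")
.REACTION_KINDS <- c("internal", "transport", "exchange", "biomass", "maintenance")
.ROLE_NAMES <- c("biomass", "light_exchange", "nitrate_exchange",
                 "maintenance", "carotene_sink")

#' Compartmentalized stoichiometric metabolic network
#'
#' Container for a constraint-based metabolic model: species with
#' compartments, reactions with signed stoichiometry, reversibility, flux
#' bounds and annotations, and a map of named roles (biomass, light and
#' nitrate exchange, maintenance ATP drain, carotenoid sink) used by the
#' scenario machinery.
#'
#' Species assigned to the `external` compartment are boundary species: they
#' are carried for bookkeeping and round-tripping but are not mass-balanced,
#' so exchange reactions appear as unbalanced columns of the stoichiometric
#' matrix returned by [buildStoichiometricMatrix()]. The sign convention is
#' negative coefficients for substrates and positive for products; exchange
#' reactions are written so that positive flux is uptake into the system.
#' All fluxes are in mmol/(g dw h); the biomass reaction flux is the specific
#' growth rate in 1/h (the biomass composition is scaled to 1 g dw per unit
#' flux).
#'
#' @slot metabolites `DataFrame` with columns `id`, `name`, `compartment`
#'   (one of cytosol, chloroplast, mitochondrion, external) and `formula`
#'   (`NA` when unknown).
#' @slot reactions `DataFrame` with columns `id`, `name`, `reversible`,
#'   `lower_bound`, `upper_bound` (`NA` until [applyBounds()] or an explicit
#'   bound is set), `ec_number`, `kegg_id` (annotation, `NA` when absent) and
#'   `kind` (internal, transport, exchange, biomass, maintenance).
#' @slot stoichiometry sparse `dgCMatrix`, species x reactions, signed
#'   coefficients; zero entries are structural zeros (never stored).
#' @slot roles named character vector mapping a subset of
#'   `r paste(.ROLE_NAMES, collapse = ", ")` to reaction ids.
#'
#' @seealso [StoichiometricNetwork()], [networkFromEquations()],
#'   [validateNetwork()], [applyBounds()]
#' @export
setClass("StoichiometricNetwork",
  representation(
    metabolites = "DataFrame",
    reactions = "DataFrame",
    stoichiometry = "dgCMatrix",
    roles = "character"
  )
)

setValidity("StoichiometricNetwork", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  S <- object@stoichiometry
  need <- setdiff(c("id", "name", "compartment", "formula"), colnames(met))
  if (length(need)) {
    return(paste("metabolites lack column(s):", paste(need, collapse = ", ")))
  }
  need <- setdiff(c("id", "name", "reversible", "lower_bound", "upper_bound",
                    "ec_number", "kegg_id", "kind"), colnames(rxn))
  if (length(need)) {
    return(paste("reactions lack column(s):", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(met$id)) {
    msg <- c(msg, paste("duplicated metabolite id:",
                        paste(unique(met$id[duplicated(met$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn$id)) {
    msg <- c(msg, paste("duplicated reaction id:",
                        paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(met$compartment), .COMPARTMENTS)
  if (length(bad)) {
    msg <- c(msg, paste("unknown compartment:", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(rxn$kind), .REACTION_KINDS)
  if (length(bad)) {
    msg <- c(msg, paste("unknown reaction kind:", paste(bad, collapse = ", ")))
  }
  if (!identical(dim(S), c(nrow(met), nrow(rxn)))) {
    msg <- c(msg, "stoichiometry dimensions do not match metabolites x reactions")
  } else {
    if (!identical(rownames(S), as.character(met$id)) ||
        !identical(colnames(S), as.character(rxn$id))) {
      msg <- c(msg, "stoichiometry dimnames must equal metabolite and reaction ids")
    }
  }
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  bad <- which(!is.na(lb) & !is.na(ub) & lb > ub)
  if (length(bad)) {
    msg <- c(msg, paste("lower_bound > upper_bound for:",
                        paste(rxn$id[bad], collapse = ", ")))
  }
  bad <- which(!rxn$reversible & !is.na(lb) & lb < 0)
  if (length(bad)) {
    msg <- c(msg, paste("irreversible reaction with negative lower bound:",
                        paste(rxn$id[bad], collapse = ", ")))
  }
  if (length(object@roles)) {
    if (is.null(names(object@roles)) || any(!nzchar(names(object@roles)))) {
      msg <- c(msg, "roles must be a named character vector")
    } else {
      bad <- setdiff(names(object@roles), .ROLE_NAMES)
      if (length(bad)) {
        msg <- c(msg, paste("unknown role:", paste(bad, collapse = ", ")))
      }
      missing <- setdiff(object@roles, rxn$id)
      if (length(missing)) {
        msg <- c(msg, paste("role points at unknown reaction:",
                            paste(missing, collapse = ", ")))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ordered linear objective specification
#'
#' One or more maximisation stages, each a named numeric vector of weights
#' over reaction ids (or role names, resolved against the network at solve
#' time). A single stage is ordinary FBA; several stages are solved
#' lexicographically by [solveLexicographic()]: each stage is maximised with
#' every earlier stage's optimum anchored as an equality constraint.
#'
#' @slot stages list of named numeric vectors, each non-empty.
#' @seealso [objectiveSpec()], [solveFBA()], [solveLexicographic()]
#' @export
setClass("ObjectiveSpec", representation(stages = "list"))

setValidity("ObjectiveSpec", function(object) {
  st <- object@stages
  if (!length(st)) return("at least one objective stage is required")
  for (i in seq_along(st)) {
    w <- st[[i]]
    if (!is.numeric(w) || !length(w) || is.null(names(w)) ||
        any(!nzchar(names(w))) || any(!is.finite(w))) {
      return(sprintf("stage %d must be a non-empty named finite numeric vector", i))
    }
  }
  TRUE
})

#' Flux scenario: driven exchange rates plus an objective
#'
#' Encodes one light-by-nutrient condition: a photon uptake rate for the
#' light exchange reaction, a nitrate uptake rate for the nitrate exchange,
#' a fixed maintenance-ATP drain, the bound mode for the driven exchanges
#' (`"capped"` = 0..value, `"fixed"` = lb = ub = value), an ordered
#' objective, and arbitrary extra per-reaction bound overrides. Rates with
#' value `NA` leave the corresponding reaction untouched, so a scenario can
#' also be a pure bag of overrides for toy models.
#'
#' @slot label scenario label (canonical scenarios are "A".."H").
#' @slot lightFlux photon uptake rate, mmol/(g dw h), or `NA`.
#' @slot nitrateFlux nitrate uptake rate, mmol/(g dw h), or `NA`.
#' @slot maintenanceFlux maintenance ATP drain, mmol/(g dw h), or `NA`.
#' @slot boundMode named character, entries `light` and `nitrate`, each
#'   `"capped"` or `"fixed"` (maintenance is always fixed).
#' @slot objective an [ObjectiveSpec-class].
#' @slot overrides named list of `c(lb, ub)` pairs keyed by reaction id.
#' @seealso [makeScenario()], [fluxScenario()], [runScenarios()]
#' @export
setClass("FluxScenario",
  representation(
    label = "character",
    lightFlux = "numeric",
    nitrateFlux = "numeric",
    maintenanceFlux = "numeric",
    boundMode = "character",
    objective = "ObjectiveSpec",
    overrides = "list"
  )
)

setValidity("FluxScenario", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  for (s in c("lightFlux", "nitrateFlux", "maintenanceFlux")) {
    v <- slot(object, s)
    if (length(v) != 1L) msg <- c(msg, paste(s, "must be length 1"))
    else if (!is.na(v) && v < 0) msg <- c(msg, paste(s, "must be non-negative"))
  }
  bm <- object@boundMode
  if (!all(c("light", "nitrate") %in% names(bm)) ||
      !all(bm %in% c("capped", "fixed"))) {
    msg <- c(msg, "boundMode must name 'light' and 'nitrate', values 'capped' or 'fixed'")
  }
  ov <- object@overrides
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
      msg <- c(msg, "overrides must be named by reaction id")
    }
    for (id in names(ov)) {
      p <- ov[[id]]
      if (!is.numeric(p) || length(p) != 2L || any(is.na(p)) || p[1] > p[2]) {
        msg <- c(msg, sprintf("override for '%s' must be c(lb, ub) with lb <= ub", id))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of a flux balance analysis
#'
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @slot stageValues optimal value of each objective stage (empty unless
#'   status is optimal).
#' @slot flux named optimal flux vector, mmol/(g dw h) (one vertex of the
#'   optimal face; the objective values, not the vertex, are the contract).
#' @slot mu growth rate in 1/h (flux through the biomass role, `NA` if the
#'   network has none).
#' @slot namedFluxes fluxes through all reactions with named roles.
#' @slot unboundedSupport reaction ids carrying an unbounded ray when
#'   status is `"unbounded"`, else empty.
#' @seealso [solveFBA()], [solveLexicographic()]
#' @export
setClass("FBAResult",
  representation(
    status = "character",
    stageValues = "numeric",
    flux = "numeric",
    mu = "numeric",
    namedFluxes = "numeric",
    unboundedSupport = "character"
  )
)

setValidity("FBAResult", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded")) {
    return("status must be optimal, infeasible or unbounded")
  }
  TRUE
})

## ---- accessors ----

#' @rdname network-accessors
#' @export
setMethod("metabolites", "StoichiometricNetwork", function(x) x@metabolites)

#' @rdname network-accessors
#' @export
setMethod("reactions", "StoichiometricNetwork", function(x) x@reactions)

#' @rdname network-accessors
#' @export
setMethod("stoichMatrix", "StoichiometricNetwork", function(x) x@stoichiometry)

#' @rdname network-accessors
#' @export
setMethod("bounds", "StoichiometricNetwork", function(x) {
  cbind(lower = x@reactions$lower_bound, upper = x@reactions$upper_bound)
})

#' @rdname network-accessors
#' @export
setMethod("roles", "StoichiometricNetwork", function(x) x@roles)

#' @rdname network-accessors
#' @export
setReplaceMethod("roles", "StoichiometricNetwork", function(x, value) {
  x@roles <- value
  validObject(x)
  x
})

## ---- show methods ----

setMethod("show", "StoichiometricNetwork", function(object) {
  met <- object@metabolites
  ncomp <- length(unique(met$compartment[met$compartment != "external"]))
  cat(sprintf("StoichiometricNetwork: %d reactions, %d metabolites (%d balanced) in %d compartment(s)\n",
              nrow(object@reactions), nrow(met),
              sum(met$compartment != "external"), ncomp))
  kinds <- table(object@reactions$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  if (length(object@roles)) {
    cat("  roles:", paste(sprintf("%s=%s", names(object@roles), object@roles),
                          collapse = ", "), "\n")
  }
})

setMethod("show", "ObjectiveSpec", function(object) {
  cat(sprintf("ObjectiveSpec with %d stage(s):\n", length(object@stages)))
  for (i in seq_along(object@stages)) {
    w <- object@stages[[i]]
    cat(sprintf("  stage %d: max %s\n", i,
                paste(sprintf("%+g*%s", w, names(w)), collapse = " ")))
  }
})

setMethod("show", "FluxScenario", function(object) {
  cat(sprintf("FluxScenario '%s': light=%s (%s), nitrate=%s (%s), maintenance=%s (fixed), %d stage(s), %d extra override(s)\n",
              object@label,
              format(object@lightFlux), object@boundMode[["light"]],
              format(object@nitrateFlux), object@boundMode[["nitrate"]],
              format(object@maintenanceFlux),
              length(object@objective@stages), length(object@overrides)))
})

setMethod("show", "FBAResult", function(object) {
  cat(sprintf("FBAResult: %s\n", object@status))
  if (object@status == "optimal") {
    cat("  stage value(s):", paste(format(object@stageValues), collapse = ", "), "\n")
    if (!is.na(object@mu)) cat(sprintf("  growth rate mu = %g 1/h\n", object@mu))
    if (length(object@namedFluxes)) {
      cat("  named fluxes:", paste(sprintf("%s=%g", names(object@namedFluxes),
                                           object@namedFluxes), collapse = ", "), "\n")
    }
  } else if (object@status == "unbounded" && length(object@unboundedSupport)) {
    cat("  unbounded ray support:",
        paste(object@unboundedSupport, collapse = ", "), "\n")
  }
})

## ---- simple constructors ----

#' Construct an objective specification
#'
#' @param ... one named numeric vector per stage, in lexicographic order.
#'   Names are reaction ids or role names (`biomass`, `carotene_sink`, ...);
#'   role names are resolved against the network when solving.
#' @return an [ObjectiveSpec-class]
#' @examples
#' objectiveSpec(c(biomass = 1))                    # max growth
#' objectiveSpec(c(biomass = 1), c(carotene_sink = 1))  # growth, then pigment
#' @export
objectiveSpec <- function(...) {
  new("ObjectiveSpec", stages = list(...))
}

#' Construct a flux scenario
#'
#' @param label scenario label.
#' @param objective an [ObjectiveSpec-class]; default maximises the biomass
#'   role.
#' @param lightFlux,nitrateFlux,maintenanceFlux driven exchange rates in
#'   mmol/(g dw h); `NA` leaves the corresponding role untouched.
#' @param boundMode named character with entries `light` and `nitrate`,
#'   each `"capped"` (bounds 0..value) or `"fixed"` (lb = ub = value).
#'   Maintenance is always fixed (lb = ub).
#' @param overrides named list of `c(lb, ub)` bound pairs keyed by reaction
#'   id, applied after the driven rates.
#' @return a [FluxScenario-class]
#' @export
fluxScenario <- function(label = "custom",
                         objective = objectiveSpec(c(biomass = 1)),
                         lightFlux = NA_real_, nitrateFlux = NA_real_,
                         maintenanceFlux = NA_real_,
                         boundMode = c(light = "capped", nitrate = "capped"),
                         overrides = list()) {
  new("FluxScenario", label = as.character(label),
      lightFlux = as.numeric(lightFlux), nitrateFlux = as.numeric(nitrateFlux),
      maintenanceFlux = as.numeric(maintenanceFlux),
      boundMode = boundMode, objective = objective, overrides = overrides)
}
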