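#' @importFrom Matrix sparseMatrix drop0 Matrix
NULL

.asDF <- function(x) {
  if (is.data.frame(x)) S4Vectors::DataFrame(x, check.names = FALSE) else x
}

#' Construct a stoichiometric network
#'
#' @param metabolites data.frame/DataFrame with at least `id` and
#'   `compartment`; `name` defaults to `id`, `formula` to `NA`.
#' @param reactions data.frame/DataFrame with at least `id`; `name` defaults
#'   to `id`, `reversible` to `FALSE`, bounds to `NA` (set later by
#'   [applyBounds()]), `ec_number`/`kegg_id` to `NA`, `kind` to `"internal"`.
#' @param stoichiometry either a species-by-reactions matrix (dense or
#'   sparse) with dimnames matching the ids, or a named list (one entry per
#'   reaction id) of named numeric vectors of signed coefficients over
#'   metabolite ids. Negative = consumed, positive = produced.
#' @param roles named character vector mapping roles (`biomass`,
#'   `light_exchange`, `nitrate_exchange`, `maintenance`, `carotene_sink`)
#'   to reaction ids.
#' @return a [StoichiometricNetwork-class]
#' @examples
#' net <- StoichiometricNetwork(
#'   metabolites = data.frame(id = c("A", "B"), compartment = "cytosol"),
#'   reactions = data.frame(id = c("R1", "R2", "R3"),
#'                          kind = c("exchange", "internal", "exchange")),
#'   stoichiometry = list(R1 = c(A = 1), R2 = c(A = -1, B = 1), R3 = c(B = -1))
#' )
#' net
#' @export
StoichiometricNetwork <- function(metabolites, reactions, stoichiometry,
                                  roles = character()) {
  met <- .asDF(as.data.frame(metabolites, optional = TRUE))
  rxn <- .asDF(as.data.frame(reactions, optional = TRUE))
  if (is.null(met$id)) stop("metabolites must have an 'id' column")
  if (is.null(rxn$id)) stop("reactions must have an 'id' column")
  met$id <- as.character(met$id)
  rxn$id <- as.character(rxn$id)
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$compartment)) stop("metabolites must have a 'compartment' column")
  if (is.null(met$formula)) met$formula <- NA_character_
  met <- met[, c("id", "name", "compartment", "formula")]
  if (is.null(rxn$name)) rxn$name <- rxn$id
  if (is.null(rxn$reversible)) rxn$reversible <- FALSE
  if (is.null(rxn$lower_bound)) rxn$lower_bound <- NA_real_
  if (is.null(rxn$upper_bound)) rxn$upper_bound <- NA_real_
  if (is.null(rxn$ec_number)) rxn$ec_number <- NA_character_
  if (is.null(rxn$kegg_id)) rxn$kegg_id <- NA_character_
  if (is.null(rxn$kind)) rxn$kind <- "internal"
  rxn$lower_bound <- as.numeric(rxn$lower_bound)
  rxn$upper_bound <- as.numeric(rxn$upper_bound)
  rxn <- rxn[, c("id", "name", "reversible", "lower_bound", "upper_bound",
                 "ec_number", "kegg_id", "kind")]
  rownames(met) <- NULL
  rownames(rxn) <- NULL

  if (is.list(stoichiometry) && !is.matrix(stoichiometry)) {
    S <- .stoichFromList(stoichiometry, met$id, rxn$id)
  } else {
    S <- drop0(Matrix(as.matrix(stoichiometry), sparse = TRUE))
    if (is.null(rownames(S)) || is.null(colnames(S))) {
      if (!identical(dim(S), c(nrow(met), nrow(rxn)))) {
        stop("stoichiometry matrix dimensions do not match metabolites x reactions")
      }
      dimnames(S) <- list(met$id, rxn$id)
    }
    S <- as(S, "CsparseMatrix")
  }
  new("StoichiometricNetwork", metabolites = met, reactions = rxn,
      stoichiometry = as(S, "dgCMatrix"), roles = roles)
}

.stoichFromList <- function(stoich, metIds, rxnIds) {
  if (is.null(names(stoich)) || !setequal(names(stoich), rxnIds)) {
    stop("stoichiometry list must have exactly one entry per reaction id")
  }
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(rxnIds)) {
    co <- stoich[[rxnIds[j]]]
    co <- co[co != 0]
    if (!length(co)) next
    unknown <- setdiff(names(co), metIds)
    if (length(unknown)) {
      stop(sprintf("reaction '%s' references unknown metabolite id(s): %s",
                   rxnIds[j], paste(unknown, collapse = ", ")))
    }
    ii <- c(ii, match(names(co), metIds))
    jj <- c(jj, rep.int(j, length(co)))
    xx <- c(xx, as.numeric(co))
  }
  sparseMatrix(i = ii, j = jj, x = xx,
               dims = c(length(metIds), length(rxnIds)),
               dimnames = list(metIds, rxnIds))
}

#' Build the stoichiometric matrix S
#'
#' Returns the dense metabolites-by-reactions matrix over *balanced* species
#' only: metabolites in the `external` compartment are boundary species and
#' are excluded, so exchange reactions appear as unbalanced columns. Entry
#' (i, j) is the signed coefficient of metabolite i in reaction j.
#'
#' @param network a [StoichiometricNetwork-class]
#' @param warnOrphans warn about balanced metabolites participating in no
#'   reaction (their rows are all zero)?
#' @return numeric matrix with dimnames (balanced metabolite ids x reaction
#'   ids)
#' @examples
#' net <- networkFromEquations(c(R1 = "-> A[c]", R2 = "A[c] -> B[c]",
#'                               R3 = "B[c] ->"))
#' buildStoichiometricMatrix(net)
#' @export
buildStoichiometricMatrix <- function(network, warnOrphans = TRUE) {
  stopifnot(is(network, "StoichiometricNetwork"))
  met <- network@metabolites
  keep <- met$compartment != "external"
  S <- as.matrix(network@stoichiometry[keep, , drop = FALSE])
  if (warnOrphans && nrow(S)) {
    orphan <- rownames(S)[rowSums(S != 0) == 0L]
    if (length(orphan)) {
      warning("metabolite(s) participating in no reaction: ",
              paste(orphan, collapse = ", "))
    }
  }
  S
}

#' Build a network from reaction equation strings
#'
#' Convenience constructor: parses each equation with
#' [parseReactionEquation()], infers the metabolite set (compartments from
#' bracket tags via `compartmentMap`; untagged species go to the cytosol) and
#' classifies reaction kinds (`exchange` when one side is empty, `transport`
#' when a reaction spans two compartments, else `internal`; override with
#' the `kind` argument).
#'
#' @param equations named character vector, names are reaction ids.
#' @param kind optional character vector (recycled) of reaction kinds
#'   overriding the inference; `NA` entries keep the inferred kind.
#' @param ec_number,kegg_id optional annotation vectors aligned with
#'   `equations`.
#' @param roles named character vector of role assignments.
#' @param compartmentMap named character mapping compartment tags to the
#'   canonical compartments, see [defaultCompartmentMap()].
#' @return a [StoichiometricNetwork-class]
#' @examples
#' networkFromEquations(c(Ex1 = "-> glc[c]",
#'                        R1 = "glc[c] + 2 atp[c] -> g6p[c] + 2 adp[c]"))
#' @export
networkFromEquations <- function(equations, kind = NA_character_,
                                 ec_number = NA_character_,
                                 kegg_id = NA_character_,
                                 roles = character(),
                                 compartmentMap = defaultCompartmentMap()) {
  if (is.null(names(equations)) || any(!nzchar(names(equations)))) {
    stop("equations must be a named character vector (names = reaction ids)")
  }
  n <- length(equations)
  kind <- rep_len(kind, n)
  ec_number <- rep_len(ec_number, n)
  kegg_id <- rep_len(kegg_id, n)
  parsed <- lapply(equations, parseReactionEquation)
  metIds <- unique(unlist(lapply(parsed, function(p) names(p$stoichiometry))))
  comp <- vapply(metIds, function(id) {
    tag <- sub("^.*\\[([^][]*)\\]\\s*$", "\\1", id)
    if (identical(tag, id)) "cytosol" else .mapCompartment(tag, compartmentMap, id)
  }, character(1))
  inferKind <- function(p) {
    co <- p$stoichiometry
    cps <- unique(comp[names(co)])
    cps <- setdiff(cps, "external")
    if (all(co > 0) || all(co < 0) || any(comp[names(co)] == "external")) "exchange"
    else if (length(cps) > 1L) "transport"
    else "internal"
  }
  kinds <- ifelse(is.na(kind), vapply(parsed, inferKind, character(1)), kind)
  StoichiometricNetwork(
    metabolites = data.frame(id = metIds, compartment = unname(comp)),
    reactions = data.frame(id = names(equations),
                           reversible = vapply(parsed, `[[`, logical(1), "reversible"),
                           ec_number = ec_number, kegg_id = kegg_id,
                           kind = kinds),
    stoichiometry = lapply(parsed, `[[`, "stoichiometry"),
    roles = roles
  )
}

.mapCompartment <- function(tag, compartmentMap, subject) {
  hit <- compartmentMap[tolower(tag)]
  if (is.na(hit)) {
    stop(sprintf("unknown compartment id '%s' (at '%s'); extend the compartment map",
                 tag, subject))
  }
  unname(hit)
}

#' Default compartment-identifier mapping
#'
#' Maps the compartment identifiers commonly used in algal models onto the
#' four canonical compartments (cytosol, chloroplast, mitochondrion,
#' external). Used by [networkFromEquations()] and [readSBML()]; pass an
#' extended copy to handle other naming schemes.
#'
#' @return named character vector (lower-cased id -> canonical compartment)
#' @export
defaultCompartmentMap <- function() {
  c(c = "cytosol", cyt = "cytosol", cytosol = "cytosol", cytoplasm = "cytosol",
    h = "chloroplast", chl = "chloroplast", plastid = "chloroplast",
    chloroplast = "chloroplast",
    m = "mitochondrion", mit = "mitochondrion", mito = "mitochondrion",
    mitochondrion = "mitochondrion",
    e = "external", ext = "external", b = "external", boundary = "external",
    external = "external", extracellular = "external")
}
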