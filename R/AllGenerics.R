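#' @import methods
#' @importFrom stats runif
#' @importFrom utils combn read.table write.table head
NULL

#' Accessor generics for stoichiometric networks
#'
#' `metabolites()` and `reactions()` return the row metadata of a
#' [StoichiometricNetwork-class] as `DataFrame`s; `stoichMatrix()` returns the
#' full signed stoichiometry (all species, including external boundary
#' species, times all reactions) as a sparse `dgCMatrix`; `bounds()` returns a
#' two-column matrix of lower/upper flux bounds in mmol/(g dw h); `roles()`
#' returns the named-role map (biomass, light_exchange, nitrate_exchange,
#' maintenance, carotene_sink).
#'
#' @param x a `StoichiometricNetwork`
#' @param value replacement value
#' @return see individual descriptions
#' @name network-accessors
#' @aliases metabolites reactions stoichMatrix bounds roles roles<-
NULL

#' @rdname network-accessors
#' @export
setGeneric("metabolites", function(x) standardGeneric("metabolites"))

#' @rdname network-accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname network-accessors
#' @export
setGeneric("stoichMatrix", function(x) standardGeneric("stoichMatrix"))

#' @rdname network-accessors
#' @export
setGeneric("bounds", function(x) standardGeneric("bounds"))

#' @rdname network-accessors
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname network-accessors
#' @export
setGeneric("roles<-", function(x, value) standardGeneric("roles<-"))
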