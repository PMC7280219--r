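#' Accessors for flimscore S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a \linkS4class{DecayCube}, \linkS4class{LifetimeMap},
#'   \linkS4class{BiexpFit} or \linkS4class{SeverityModel}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("decayCounts", function(object) standardGeneric("decayCounts"))
#' @rdname accessors
#' @export
setMethod("decayCounts", "DecayCube", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("timeBinNs", function(object) standardGeneric("timeBinNs"))
#' @rdname accessors
#' @export
setMethod("timeBinNs", "DecayCube", function(object) object@time_bin_ns)

#' @rdname accessors
#' @export
setGeneric("depthUm", function(object) standardGeneric("depthUm"))
#' @rdname accessors
#' @export
setMethod("depthUm", "DecayCube", function(object) object@depth_um)
#' @rdname accessors
#' @export
setMethod("depthUm", "LifetimeMap", function(object) object@depth_um)

#' @rdname accessors
#' @export
setGeneric("validityMask", function(object) standardGeneric("validityMask"))
#' @rdname accessors
#' @export
setMethod("validityMask", "LifetimeMap", function(object) object@mask)

#' Extract one per-pixel parameter plane from a LifetimeMap
#'
#' @param object a \linkS4class{LifetimeMap}
#' @param layer one of "tau1", "tau2", "a1", "a2", "mean_lifetime", "p1",
#'   "p2", "chi2", "n_photons"
#' @return numeric matrix with NA on masked pixels
#' @export
setGeneric("mapLayer", function(object, layer) standardGeneric("mapLayer"))
#' @rdname mapLayer
#' @export
setMethod("mapLayer", "LifetimeMap", function(object, layer) {
  layer <- match.arg(layer, c("tau1", "tau2", "a1", "a2", "mean_lifetime",
                              "p1", "p2", "chi2", "n_photons"))
  slot(object, layer)
})

#' @rdname accessors
#' @export
setGeneric("rotationMatrix", function(object) standardGeneric("rotationMatrix"))
#' @rdname accessors
#' @export
setMethod("rotationMatrix", "SeverityModel", function(object)
  object@rotation)

#' @rdname accessors
#' @export
setGeneric("explainedVarianceRatio",
           function(object) standardGeneric("explainedVarianceRatio"))
#' @rdname accessors
#' @export
setMethod("explainedVarianceRatio", "SeverityModel", function(object)
  object@explained_variance_ratio)

#' @rdname accessors
#' @export
setGeneric("featureSchema", function(object) standardGeneric("featureSchema"))
#' @rdname accessors
#' @export
setMethod("featureSchema", "SeverityModel", function(object) object@features)
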