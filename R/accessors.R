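#' Accessors for MethylStudy and StratumView
#'
#' \code{betas} returns the probes x samples beta matrix; \code{sampleSheet}
#' the sample metadata; \code{speciesTraits} the trait table;
#' \code{cpgAnnotation} the probe annotation. For \code{StratumView}:
#' \code{stratumId}, \code{sampleAges} (years), \code{relAges} (unitless),
#' \code{methylMeans} (per-sample mean beta), \code{scaledMethyl}
#' (standardized response), \code{maxLifespan} (years) and
#' \code{ageInterval} (relative-age bounds).
#'
#' @param object a \linkS4class{MethylStudy} or \linkS4class{StratumView}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("betas", function(object) standardGeneric("betas"))
#' @rdname accessors
#' @export
setMethod("betas", "MethylStudy", function(object)
  SummarizedExperiment::assay(object, "beta"))

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(object) standardGeneric("sampleSheet"))
#' @rdname accessors
#' @export
setMethod("sampleSheet", "MethylStudy", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @rdname accessors
#' @export
setGeneric("speciesTraits", function(object) standardGeneric("speciesTraits"))
#' @rdname accessors
#' @export
setMethod("speciesTraits", "MethylStudy", function(object)
  as.data.frame(object@traits))

#' @rdname accessors
#' @export
setGeneric("cpgAnnotation", function(object) standardGeneric("cpgAnnotation"))
#' @rdname accessors
#' @export
setMethod("cpgAnnotation", "MethylStudy", function(object)
  as.data.frame(SummarizedExperiment::rowData(object)))

#' @rdname accessors
#' @export
setGeneric("stratumId", function(object) standardGeneric("stratumId"))
#' @rdname accessors
#' @export
setMethod("stratumId", "StratumView", function(object) object@stratumId)

#' @rdname accessors
#' @export
setGeneric("sampleAges", function(object) standardGeneric("sampleAges"))
#' @rdname accessors
#' @export
setMethod("sampleAges", "StratumView", function(object) object@ages)

#' @rdname accessors
#' @export
setGeneric("relAges", function(object) standardGeneric("relAges"))
#' @rdname accessors
#' @export
setMethod("relAges", "StratumView", function(object) object@relAges)

#' @rdname accessors
#' @export
setGeneric("methylMeans", function(object) standardGeneric("methylMeans"))
#' @rdname accessors
#' @export
setMethod("methylMeans", "StratumView", function(object) object@methyl)

#' @rdname accessors
#' @export
setGeneric("scaledMethyl", function(object) standardGeneric("scaledMethyl"))
#' @rdname accessors
#' @export
setMethod("scaledMethyl", "StratumView", function(object) object@scaled)

#' @rdname accessors
#' @export
setGeneric("maxLifespan", function(object) standardGeneric("maxLifespan"))
#' @rdname accessors
#' @export
setMethod("maxLifespan", "StratumView", function(object) object@L)

#' @rdname accessors
#' @export
setGeneric("ageInterval", function(object) standardGeneric("ageInterval"))
#' @rdname accessors
#' @export
setMethod("ageInterval", "StratumView", function(object) object@interval)
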