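#' @name parpvus-accessors
#' @title Accessors for parpvus S4 containers
#' @description Slot accessors: \code{patients()} and \code{variants()} return
#'   the cohort tables, \code{cohortLabel()} the cohort name,
#'   \code{finalLabel()}, \code{perModelLabels()} and \code{rationale()} the
#'   pieces of a \linkS4class{ClassificationResult}, and \code{kmMedian()} the
#'   median of a \linkS4class{KMCurve}.
#' @param object a parpvus S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname parpvus-accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))

#' @rdname parpvus-accessors
#' @export
setGeneric("variants", function(object) standardGeneric("variants"))

#' @rdname parpvus-accessors
#' @export
setGeneric("cohortLabel", function(object) standardGeneric("cohortLabel"))

#' @rdname parpvus-accessors
#' @export
setGeneric("finalLabel", function(object) standardGeneric("finalLabel"))

#' @rdname parpvus-accessors
#' @export
setGeneric("perModelLabels",
           function(object) standardGeneric("perModelLabels"))

#' @rdname parpvus-accessors
#' @export
setGeneric("rationale", function(object) standardGeneric("rationale"))

#' @rdname parpvus-accessors
#' @export
setGeneric("kmMedian", function(object) standardGeneric("kmMedian"))

#' Highest-priority known variant class of a case or cohort
#'
#' Reduces the known (reported) classes of a patient's variants to a single
#' patient-level class under the precedence pathogenic > unknown > benign;
#' "probably benign" counts as benign. This is the stratification used to
#' split a cohort into benign / VUS / pathogenic survival groups.
#'
#' @param object a \linkS4class{PatientCase} or \linkS4class{ParpCohort}.
#' @return For a case, one of \code{"benign"}, \code{"unknown"},
#'   \code{"pathogenic"}; for a cohort, a named character vector over the
#'   episodes that carry at least one variant.
#' @examples
#' coh <- loadFixture("table2")
#' table(patientVariantClass(coh))
#' @export
setGeneric("patientVariantClass",
           function(object) standardGeneric("patientVariantClass"))
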