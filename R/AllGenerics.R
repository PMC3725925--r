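#' @name accessors
#' @title Accessors for vesselseg classes
#' @description Slot accessors for the S4 containers; user code should use
#'   these rather than reach into slots.
#' @param object an object of the documented class.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("fovMask", function(object) standardGeneric("fovMask"))
#' @rdname accessors
#' @export
setGeneric("truthMap", function(object) standardGeneric("truthMap"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("vesselMap", function(object) standardGeneric("vesselMap"))
#' @rdname accessors
#' @export
setGeneric("levelSet", function(object) standardGeneric("levelSet"))
#' @rdname accessors
#' @export
setGeneric("energyTrace", function(object) standardGeneric("energyTrace"))
#' @rdname accessors
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))

#' @rdname accessors
#' @export
setMethod("intensities", "RetinalSample", function(object) object@image)
#' @rdname accessors
#' @export
setMethod("fovMask", "RetinalSample", function(object) object@fov)
#' @rdname accessors
#' @export
setMethod("truthMap", "RetinalSample", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("sampleId", "RetinalSample", function(object) object@sampleId)

#' @rdname accessors
#' @export
setMethod("vesselMap", "SegmentationResult", function(object) object@vessel)
#' @rdname accessors
#' @export
setMethod("levelSet", "SegmentationResult", function(object) object@phi)
#' @rdname accessors
#' @export
setMethod("energyTrace", "SegmentationResult",
          function(object) object@energyTrace)
#' @rdname accessors
#' @export
setMethod("classMeans", "SegmentationResult", function(object) object@mu)
#' @rdname accessors
#' @export
setMethod("converged", "SegmentationResult", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("iterations", "SegmentationResult", function(object) object@iterations)

setMethod("show", "NeighborhoodSpec", function(object) {
  w <- 2L * object@radius + 1L
  cat(sprintf("NeighborhoodSpec: %dx%d window, sigma_g^2 = %g, center %s\n",
              w, w, object@sigmaGSq,
              if (object@includeCenter) "included" else "excluded"))
})

setMethod("show", "WeightKernel", function(object) {
  cat(sprintf("WeightKernel %dx%d (sum lambda = %.12f)\n",
              nrow(object@lambda), ncol(object@lambda), sum(object@lambda)))
  print(round(object@lambda, 6))
})

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams\n")
  cat(sprintf("  mu      : %s\n", paste(signif(object@mu, 6), collapse = ", ")))
  cat(sprintf("  alpha   : %g   beta: %g   dt: %g   epsilon: %g\n",
              object@alpha, object@beta, object@dt, object@epsilon))
  show(object@spec)
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat(sprintf(
    "EnergyBreakdown: total %.6g (data %.6g, length %.6g, distance-reg %.6g)\n",
    object@total, object@dataTerm, object@lengthTerm,
    object@regularizationTerm))
})

setMethod("show", "RetinalSample", function(object) {
  cat(sprintf("RetinalSample '%s': %d x %d, FOV %d px (%.1f%%), truth %s\n",
              object@sampleId, nrow(object@image), ncol(object@image),
              sum(object@fov), 100 * mean(object@fov),
              if (is.null(object@truth)) "absent" else "present"))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: %d x %d, %d iterations (%s), %d vessel px\n",
    nrow(object@vessel), ncol(object@vessel), object@iterations,
    if (object@converged) "converged" else "not converged",
    sum(object@vessel)))
  cat(sprintf("  class means: %.3f (phi > 0), %.3f (phi < 0); vessel = %s\n",
              object@mu[1], object@mu[2], object@vesselClass))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (FOV n = %d): accuracy %.4f, sensitivity %s, specificity %.4f\n",
    object@nFov, object@accuracy,
    if (is.na(object@sensitivity)) "NA" else sprintf("%.4f", object@sensitivity),
    object@specificity))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n",
              object@tp, object@fp, object@tn, object@fn))
})
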