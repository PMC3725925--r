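#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Neighborhood specification
#'
#' Describes the square pixel neighborhood used both for the geometric
#' closeness weights and for the counting window of the region energy.
#' A radius of 1 gives the usual 3x3 window.
#'
#' @slot radius integer window radius in pixels; the window is
#'   \eqn{(2r+1)\times(2r+1)}.
#' @slot sigmaGSq positive numeric, the spatial variance \eqn{\sigma_g^2}
#'   (pixel^2) of the Gaussian closeness kernel.
#' @slot includeCenter logical; whether a pixel belongs to its own
#'   neighborhood.
#'
#' @seealso [neighborhoodSpec()], [geometricCloseness()], [mixingWeights()]
#' @export
setClass("NeighborhoodSpec",
  representation(radius = "integer", sigmaGSq = "numeric",
                 includeCenter = "logical"))

setValidity("NeighborhoodSpec", function(object) {
  msg <- character(0)
  if (length(object@radius) != 1L || is.na(object@radius) || object@radius < 1L)
    msg <- c(msg, "radius must be a single integer >= 1")
  if (length(object@sigmaGSq) != 1L || !is.finite(object@sigmaGSq) ||
      object@sigmaGSq <= 0)
    msg <- c(msg, "sigmaGSq must be a single positive number")
  if (length(object@includeCenter) != 1L || is.na(object@includeCenter))
    msg <- c(msg, "includeCenter must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a NeighborhoodSpec
#'
#' @param radius window radius in pixels (default 1, i.e. 3x3).
#' @param sigmaGSq spatial variance of the closeness kernel (default 10).
#' @param includeCenter whether the center pixel is part of its own
#'   neighborhood (default TRUE).
#' @return A [NeighborhoodSpec-class] object.
#' @examples
#' neighborhoodSpec()
#' neighborhoodSpec(radius = 2, sigmaGSq = 25)
#' @export
neighborhoodSpec <- function(radius = 1L, sigmaGSq = 10, includeCenter = TRUE) {
  new("NeighborhoodSpec", radius = as.integer(radius),
      sigmaGSq = as.numeric(sigmaGSq), includeCenter = includeCenter)
}

#' Mixing-weight kernel over a pixel neighborhood
#'
#' Holds the geometric closeness values \eqn{h} and the normalized mixing
#' weights \eqn{\lambda} on the window. The weights sum to one over the
#' neighborhood; when the center is excluded from the neighborhood its
#' \eqn{\lambda} entry is zero.
#'
#' @slot h numeric matrix of closeness values (center value 1).
#' @slot lambda numeric matrix of normalized mixing weights.
#' @seealso [mixingWeights()]
#' @export
setClass("WeightKernel",
  representation(h = "matrix", lambda = "matrix"))

setValidity("WeightKernel", function(object) {
  if (!identical(dim(object@h), dim(object@lambda)))
    return("h and lambda must have identical dimensions")
  if (any(object@h < 0) || any(object@lambda < 0))
    return("kernel entries must be nonnegative")
  TRUE
})

#' Model parameters for the two-phase segmentation energy
#'
#' @slot mu numeric of length 2: the class means (intensity units); may be NA
#'   before estimation.
#' @slot alpha nonnegative weight of the contour-length penalty.
#' @slot beta nonnegative weight of the distance-regularization term; the
#'   default 0.001 * 255^2 is calibrated to intensities on the 0--255 scale.
#' @slot dt positive time step of the gradient flow.
#' @slot epsilon positive width of the regularized Heaviside/Dirac pair
#'   (in level set units).
#' @slot spec a [NeighborhoodSpec-class].
#' @seealso [modelParams()], [segmentVessels()]
#' @export
setClass("ModelParams",
  representation(mu = "numeric", alpha = "numeric", beta = "numeric",
                 dt = "numeric", epsilon = "numeric",
                 spec = "NeighborhoodSpec"))

setValidity("ModelParams", function(object) {
  msg <- character(0)
  if (length(object@mu) != 2L) msg <- c(msg, "mu must have length 2")
  if (length(object@alpha) != 1L || is.na(object@alpha) || object@alpha < 0)
    msg <- c(msg, "alpha must be a single nonnegative number")
  if (length(object@beta) != 1L || is.na(object@beta) || object@beta < 0)
    msg <- c(msg, "beta must be a single nonnegative number")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a single positive number")
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msg <- c(msg, "epsilon must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct ModelParams
#'
#' Defaults are the reference settings for 8-bit fundus images: alpha = 1,
#' dt = 0.1, beta = 0.001 * 255^2, epsilon = 1, 3x3 neighborhood with
#' sigma_g^2 = 10.
#'
#' @param mu class means; usually left NA and estimated during evolution.
#' @param alpha contour-length weight.
#' @param beta distance-regularization weight.
#' @param dt gradient-flow time step.
#' @param epsilon Heaviside/Dirac regularization width.
#' @param spec a [NeighborhoodSpec-class].
#' @return A [ModelParams-class] object.
#' @examples
#' modelParams()
#' modelParams(alpha = 0.5, spec = neighborhoodSpec(radius = 2))
#' @export
modelParams <- function(mu = c(NA_real_, NA_real_), alpha = 1,
                        beta = 0.001 * 255^2, dt = 0.1, epsilon = 1,
                        spec = neighborhoodSpec()) {
  new("ModelParams", mu = as.numeric(mu), alpha = as.numeric(alpha),
      beta = as.numeric(beta), dt = as.numeric(dt),
      epsilon = as.numeric(epsilon), spec = spec)
}

#' Decomposition of the total segmentation energy
#'
#' @slot dataTerm region (data fidelity) energy.
#' @slot lengthTerm contour-length energy (unweighted).
#' @slot regularizationTerm distance-regularization energy (unweighted).
#' @slot total dataTerm + alpha * lengthTerm + beta * regularizationTerm.
#' @seealso [totalEnergy()]
#' @export
setClass("EnergyBreakdown",
  representation(dataTerm = "numeric", lengthTerm = "numeric",
                 regularizationTerm = "numeric", total = "numeric"))

setValidity("EnergyBreakdown", function(object) {
  if (object@lengthTerm < 0) return("lengthTerm must be nonnegative")
  if (object@regularizationTerm < 0)
    return("regularizationTerm must be nonnegative")
  TRUE
})

#' A retinal image with its FOV mask and optional ground truth
#'
#' The working representation is a plain numeric matrix of intensities
#' (rows = image rows), by default on the 0--255 scale, a logical FOV mask of
#' the same shape, and optionally a logical manual vessel map.
#'
#' @slot image numeric matrix of intensities.
#' @slot fov logical matrix; TRUE inside the field of view.
#' @slot truth logical matrix of manual vessel labels, or NULL.
#' @slot sampleId character identifier.
#' @seealso [retinalSample()], [loadSample()], [vesselPhantom()]
#' @export
setClass("RetinalSample",
  representation(image = "matrix", fov = "matrix", truth = "matrixOrNULL",
                 sampleId = "character"))

setValidity("RetinalSample", function(object) {
  msg <- character(0)
  if (!is.numeric(object@image) || !all(is.finite(object@image)))
    msg <- c(msg, "image must be a finite numeric matrix")
  if (!is.logical(object@fov))
    msg <- c(msg, "fov must be a logical matrix")
  if (!identical(dim(object@image), dim(object@fov)))
    msg <- c(msg, "image and fov must have the same shape")
  else if (!any(object@fov))
    msg <- c(msg, "fov must contain at least one TRUE pixel")
  if (!is.null(object@truth)) {
    if (!is.logical(object@truth))
      msg <- c(msg, "truth must be a logical matrix or NULL")
    if (!identical(dim(object@image), dim(object@truth)))
      msg <- c(msg, "image and truth must have the same shape")
  }
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a RetinalSample
#'
#' @param image numeric intensity matrix.
#' @param fov logical FOV mask; defaults to the full frame.
#' @param truth optional logical vessel ground truth.
#' @param sampleId identifier string.
#' @return A [RetinalSample-class] object.
#' @export
retinalSample <- function(image, fov = NULL, truth = NULL,
                          sampleId = "sample") {
  image <- as.matrix(image)
  storage.mode(image) <- "double"
  if (is.null(fov)) fov <- matrix(TRUE, nrow(image), ncol(image))
  new("RetinalSample", image = image, fov = fov, truth = truth,
      sampleId = sampleId)
}

#' Result of a level set vessel segmentation
#'
#' @slot vessel logical matrix; TRUE at pixels labeled vessel.
#' @slot phi numeric matrix, the final level set function.
#' @slot energyTrace data.frame with one row per iteration and columns
#'   data, length, regularization, total.
#' @slot iterations number of iterations performed.
#' @slot converged logical; whether the stationarity test was met.
#' @slot mu numeric length 2, the final class means (phi > 0 class first).
#' @slot vesselClass "darker" or "brighter": which class was mapped to vessel.
#' @seealso [segmentVessels()]
#' @export
setClass("SegmentationResult",
  representation(vessel = "matrix", phi = "matrix", energyTrace = "data.frame",
                 iterations = "integer", converged = "logical",
                 mu = "numeric", vesselClass = "character"))

setValidity("SegmentationResult", function(object) {
  msg <- character(0)
  if (!is.logical(object@vessel)) msg <- c(msg, "vessel must be logical")
  if (!identical(dim(object@vessel), dim(object@phi)))
    msg <- c(msg, "vessel and phi must have the same shape")
  if (!all(is.finite(object@phi))) msg <- c(msg, "phi must be finite")
  if (nrow(object@energyTrace) != object@iterations)
    msg <- c(msg, "energyTrace must have one row per iteration")
  if (length(msg)) msg else TRUE
})

#' Segmentation quality inside the field of view
#'
#' Confusion counts and derived rates restricted to FOV pixels; vessels are
#' the positive class. Sensitivity is NA when the truth has no vessel pixels
#' inside the FOV.
#'
#' @slot accuracy (tp + tn) / nFov.
#' @slot sensitivity tp / (tp + fn), the vessel true-positive rate.
#' @slot specificity tn / (tn + fp), the background true-negative rate.
#' @slot tp,fp,tn,fn confusion counts.
#' @slot nFov number of FOV pixels.
#' @seealso [scoreSegmentation()]
#' @export
setClass("MetricsReport",
  representation(accuracy = "numeric", sensitivity = "numeric",
                 specificity = "numeric", tp = "integer", fp = "integer",
                 tn = "integer", fn = "integer", nFov = "integer"))

setValidity("MetricsReport", function(object) {
  if (object@tp + object@fp + object@tn + object@fn != object@nFov)
    return("confusion counts must sum to nFov")
  if (object@nFov < 1L) return("nFov must be positive")
  TRUE
})
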