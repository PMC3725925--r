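#' Neighborhood count field
#'
#' For each pixel j, the number of pixels i whose neighborhood window
#' contains j (equivalently, the number of in-domain pixels in j's own
#' window, since the window is symmetric). Interior pixels have the full
#' window count \eqn{(2r+1)^2} (minus one if the center is excluded); the
#' count shrinks near the borders, where out-of-domain pixels simply do not
#' exist.
#'
#' @param dim integer length 2: image dimensions (rows, cols).
#' @param spec a [NeighborhoodSpec-class].
#' @return Numeric matrix of counts.
#' @export
neighborCount <- function(dim, spec = neighborhoodSpec()) {
  zeroPadConv(matrix(1, dim[1], dim[2]), windowIndicator(spec))
}

#' Per-class region energy density
#'
#' The neighborhood-weighted squared deviation from a class mean:
#' \eqn{e_k(x_j) = c(j) (x_j - \mu_k)^2} where \eqn{c(j)} is the
#' neighborhood count of pixel j (see [neighborCount()]). The difference
#' \eqn{e_2 - e_1} is the data force that drives the level set evolution.
#'
#' @param image numeric intensity matrix or [RetinalSample-class].
#' @param mu_k class mean.
#' @param spec a [NeighborhoodSpec-class].
#' @return Numeric matrix of nonnegative energy densities.
#' @examples
#' energyDensity(matrix(5, 3, 3), mu_k = 2)   # 81 at the interior pixel
#' @export
energyDensity <- function(image, mu_k, spec = neighborhoodSpec()) {
  image <- asIntensityMatrix(image)
  neighborCount(dim(image), spec) * (image - mu_k)^2
}

#' Region (data) energy of a two-phase partition
#'
#' \deqn{\sum_j e_1(x_j) H_\epsilon(\phi_j) + \sum_j e_2(x_j)(1 - H_\epsilon(\phi_j))}
#' with the regularized Heaviside membership of the \eqn{\phi > 0} region.
#'
#' @param image numeric intensity matrix or [RetinalSample-class].
#' @param phi level set matrix, same shape as the image.
#' @param params a [ModelParams-class] with both class means set.
#' @return A single nonnegative number.
#' @export
dataEnergy <- function(image, phi, params) {
  image <- asIntensityMatrix(image)
  if (!identical(dim(image), dim(phi)))
    stop("phi must have the same shape as the image")
  if (anyNA(params@mu)) stop("params@mu must be set to compute the energy")
  H <- regHeaviside(phi, params@epsilon)
  e1 <- energyDensity(image, params@mu[1], params@spec)
  e2 <- energyDensity(image, params@mu[2], params@spec)
  sum(e1 * H) + sum(e2 * (1 - H))
}

#' Contour-length energy
#'
#' \deqn{\sum_i \delta_\epsilon(\phi_i) |\nabla \phi_i|}
#' a smoothed measure of the arc length of the zero level contour.
#'
#' @param phi level set matrix.
#' @param epsilon Dirac regularization width.
#' @return A single nonnegative number.
#' @export
lengthEnergy <- function(phi, epsilon = 1) {
  sum(regDirac(phi, epsilon) * gradMagnitude(phi))
}

#' Distance-regularization energy
#'
#' \deqn{\sum_i \tfrac12 (|\nabla \phi_i| - 1)^2}
#' Zero exactly when phi is a (sampled) signed distance function; penalizing
#' this deviation keeps the level set well conditioned without explicit
#' reinitialization.
#'
#' @param phi level set matrix.
#' @return A single nonnegative number.
#' @export
distRegEnergy <- function(phi) {
  sum(0.5 * (gradMagnitude(phi) - 1)^2)
}

#' Total segmentation energy
#'
#' Assembles data + alpha * length + beta * distance-regularization.
#'
#' @param image numeric intensity matrix or [RetinalSample-class].
#' @param phi level set matrix.
#' @param params a [ModelParams-class] with class means set.
#' @return An [EnergyBreakdown-class].
#' @export
totalEnergy <- function(image, phi, params) {
  dataT <- dataEnergy(image, phi, params)
  lenT <- lengthEnergy(phi, params@epsilon)
  regT <- distRegEnergy(phi)
  new("EnergyBreakdown", dataTerm = dataT, lengthTerm = lenT,
      regularizationTerm = regT,
      total = dataT + params@alpha * lenT + params@beta * regT)
}
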