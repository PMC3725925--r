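#' Geometric closeness kernel
#'
#' Gaussian spatial closeness between a pixel and its neighbors: for a window
#' offset \eqn{(du, dv)} the value is
#' \eqn{h = \exp(-(du^2 + dv^2) / (2\sigma_g^2))}. The kernel is maximal (1)
#' at the center and decreases with distance; \eqn{\sigma_g^2} sets how fast.
#'
#' @param spec a [NeighborhoodSpec-class].
#' @return Numeric matrix of size \eqn{(2r+1)\times(2r+1)}.
#' @examples
#' geometricCloseness(neighborhoodSpec())          # 3x3, sigma_g^2 = 10
#' @export
geometricCloseness <- function(spec = neighborhoodSpec()) {
  validObject(spec)
  r <- spec@radius
  off <- seq.int(-r, r)
  d2 <- outer(off^2, off^2, `+`)
  exp(-d2 / (2 * spec@sigmaGSq))
}

#' Normalized mixing weights over a neighborhood
#'
#' Normalizes the geometric closeness kernel so the weights sum to one over
#' the neighborhood: \eqn{\lambda_{ij} = h_{ij} / \sum_{j \in N(i)} h_{ij}}.
#' When the center pixel is not part of its own neighborhood, its weight is
#' zero and the normalization runs over the remaining offsets.
#'
#' These weights couple a pixel's likelihood to its neighbors' class
#' assignments; they are constants of the model (they drop out of the energy
#' minimized downstream) but are exposed for completeness and for weighted
#' variants.
#'
#' @param spec a [NeighborhoodSpec-class].
#' @return A [WeightKernel-class] with slots `h` and `lambda`.
#' @examples
#' k <- mixingWeights(neighborhoodSpec())
#' sum(k@lambda)   # 1
#' @export
mixingWeights <- function(spec = neighborhoodSpec()) {
  h <- geometricCloseness(spec)
  member <- windowIndicator(spec) > 0
  total <- sum(h[member])
  if (total <= 0) stop("degenerate closeness kernel: all weights zero")
  lambda <- matrix(0, nrow(h), ncol(h))
  lambda[member] <- h[member] / total
  new("WeightKernel", h = h, lambda = lambda)
}

#' Binary neighborhood window
#'
#' The indicator \eqn{\rho} of the neighborhood: 1 at offsets belonging to
#' the window, 0 outside (here, only the center can be outside). Used as the
#' counting kernel of the region energy.
#'
#' @param spec a [NeighborhoodSpec-class].
#' @return Numeric 0/1 matrix of size \eqn{(2r+1)\times(2r+1)}.
#' @examples
#' windowIndicator(neighborhoodSpec(radius = 1, includeCenter = FALSE))
#' @export
windowIndicator <- function(spec = neighborhoodSpec()) {
  validObject(spec)
  w <- 2L * spec@radius + 1L
  rho <- matrix(1, w, w)
  if (!spec@includeCenter) rho[spec@radius + 1L, spec@radius + 1L] <- 0
  rho
}
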