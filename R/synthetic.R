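# Seed handling: every stochastic generator takes an explicit seed and
# restores the caller's RNG state afterwards.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic retinal vessel phantom
#'
#' Generates a ground-truthed two-class image matching the segmentation
#' model's assumptions: dark curvilinear vessel trees on a brighter disk
#' (the FOV), each class Gaussian around its mean. Centerlines are random
#' walks from the disk center with smoothly drifting heading, dilated to a
#' linearly tapering width; each branch bifurcates once. Pixel intensities
#' are mu + N(0, noiseSigma^2), clipped to [0, 255]; outside the FOV disk
#' the noise-free level is 0, as in a fundus photograph. Anatomical realism
#' is deliberately minimal: the phantom exercises the intensity model, not
#' vascular geometry.
#'
#' @param shape integer length 2 (rows, cols); default c(256, 256).
#' @param muVessel,muBackground class mean intensities (0--255 scale);
#'   defaults 80 and 180.
#' @param noiseSigma Gaussian noise standard deviation (default 10).
#' @param nBranches number of primary branches (default 6).
#' @param widthRange numeric length 2, vessel width in pixels at the root
#'   and tip (default c(2, 5); each branch tapers from a root width drawn in
#'   this range down to its minimum).
#' @param curvatureScale standard deviation of the per-step heading
#'   perturbation in radians (default 0.15).
#' @param fovRadiusFraction FOV disk radius as a fraction of min(h, w)/2
#'   (default 0.95).
#' @param seed integer seed; the sample is fully reproducible from it.
#' @return A [RetinalSample-class] with exact truth and FOV masks.
#' @examples
#' ph <- vesselPhantom(shape = c(96, 96), seed = 1)
#' ph
#' @export
vesselPhantom <- function(shape = c(256L, 256L), muVessel = 80,
                          muBackground = 180, noiseSigma = 10,
                          nBranches = 6L, widthRange = c(2, 5),
                          curvatureScale = 0.15, fovRadiusFraction = 0.95,
                          seed = 1L) {
  if (muVessel == muBackground)
    stop("muVessel and muBackground must differ")
  if (widthRange[1] < 1) stop("minimum vessel width must be >= 1 pixel")
  if (fovRadiusFraction <= 0 || fovRadiusFraction > 1)
    stop("fovRadiusFraction must be in (0, 1]")
  if (noiseSigma < 0) stop("noiseSigma must be nonnegative")
  h <- shape[1]; w <- shape[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  R <- fovRadiusFraction * min(h, w) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  fov <- (yy - cy)^2 + (xx - cx)^2 <= R^2

  withSeed(seed, {
    tree <- matrix(FALSE, h, w)
    stamp <- function(y, x, rad) {
      r0 <- max(1L, floor(y - rad)); r1 <- min(h, ceiling(y + rad))
      c0 <- max(1L, floor(x - rad)); c1 <- min(w, ceiling(x + rad))
      if (r0 > r1 || c0 > c1) return(invisible())
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - y)^2, (cc - x)^2, `+`)
      tree[rr, cc] <<- tree[rr, cc] | (d2 <= rad^2)
      invisible()
    }
    walk <- function(y, x, heading, widthFrom, widthTo, nSteps) {
      n <- 0L
      while (n < nSteps && (y - cy)^2 + (x - cx)^2 <= R^2) {
        wd <- widthFrom + (widthTo - widthFrom) * n / nSteps
        stamp(y, x, wd / 2)
        heading <- heading + stats::rnorm(1, 0, curvatureScale)
        y <- y + sin(heading)
        x <- x + cos(heading)
        n <- n + 1L
      }
    }
    for (b in seq_len(nBranches)) {
      heading0 <- stats::runif(1, 0, 2 * pi)
      rootWidth <- stats::runif(1, widthRange[1], widthRange[2])
      walk(cy, cx, heading0, rootWidth, widthRange[1], round(1.2 * R))
      # one bifurcation per branch: a daughter leaves the parent's path at a
      # random radial position with a deflected heading and thinner caliber
      tSplit <- stats::runif(1, 0.3, 0.8)
      walk(cy + tSplit * R * sin(heading0), cx + tSplit * R * cos(heading0),
           heading0 + sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.8),
           rootWidth * (1 - tSplit) + widthRange[1] * tSplit, widthRange[1],
           round(0.6 * R))
    }
    truth <- tree & fov
    if (!any(truth))
      stop("degenerate phantom: vessel tree empty after FOV clipping")
    img <- ifelse(fov, muBackground, 0)
    img[truth] <- muVessel
    img <- img + stats::rnorm(h * w, 0, noiseSigma)
    img <- pmin(pmax(img, 0), 255)
    retinalSample(matrix(img, h, w), fov = fov, truth = truth,
                  sampleId = sprintf("phantom-seed%d", seed))
  })
}

#' Minimal two-class fixture
#'
#' Left half at one intensity, right half at another, plus Gaussian noise;
#' the truth map marks the darker half as vessel (or the brighter one when
#' `vesselClass = "brighter"`). FOV is the full frame.
#'
#' @param shape integer length 2 (rows, cols); width must be >= 2.
#' @param vLeft,vRight intensities of the two halves.
#' @param noiseSigma Gaussian noise sd (default 0).
#' @param seed integer seed for the noise.
#' @param vesselClass which half the truth labels as vessel.
#' @return A [RetinalSample-class].
#' @examples
#' twoBlockImage(c(8, 8), 50, 200)
#' @export
twoBlockImage <- function(shape = c(64L, 64L), vLeft = 50, vRight = 200,
                          noiseSigma = 0, seed = 1L,
                          vesselClass = c("darker", "brighter")) {
  vesselClass <- match.arg(vesselClass)
  h <- shape[1]; w <- shape[2]
  if (w < 2L) stop("width must be >= 2")
  img <- matrix(vLeft, h, w)
  img[, (w %/% 2L + 1L):w] <- vRight
  if (noiseSigma > 0)
    img <- withSeed(seed, img + stats::rnorm(h * w, 0, noiseSigma))
  leftIsVessel <- xor(vLeft < vRight, vesselClass == "brighter")
  truth <- matrix(FALSE, h, w)
  if (vLeft != vRight)
    truth[, if (leftIsVessel) seq_len(w %/% 2L) else (w %/% 2L + 1L):w] <- TRUE
  retinalSample(img, truth = truth,
                sampleId = sprintf("twoblock-%g-%g", vLeft, vRight))
}
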