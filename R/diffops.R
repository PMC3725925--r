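# Finite-difference primitives shared by the energy and evolution code.
# Conventions: central differences, replicate (Neumann) boundary handling,
# gradient magnitudes floored at 1e-10 wherever they appear in a denominator.

.GRAD_FLOOR <- 1e-10

# shift with replicated borders; dr/dc are source offsets so that
# out[i,j] = m[i+dr, j+dc] clipped to the domain
shiftReplicate <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# central-difference gradient; gy along rows (first index), gx along columns
gradCentral <- function(m) {
  list(gy = (shiftReplicate(m, 1L, 0L) - shiftReplicate(m, -1L, 0L)) / 2,
       gx = (shiftReplicate(m, 0L, 1L) - shiftReplicate(m, 0L, -1L)) / 2)
}

gradMagnitude <- function(m) {
  g <- gradCentral(m)
  sqrt(g$gx^2 + g$gy^2)
}

# 5-point Laplacian with replicated borders
laplacian5 <- function(m) {
  shiftReplicate(m, 1L, 0L) + shiftReplicate(m, -1L, 0L) +
    shiftReplicate(m, 0L, 1L) + shiftReplicate(m, 0L, -1L) - 4 * m
}

# curvature div(grad phi / |grad phi|)
curvatureDiv <- function(m) {
  g <- gradCentral(m)
  mag <- pmax(sqrt(g$gx^2 + g$gy^2), .GRAD_FLOOR)
  nx <- g$gx / mag
  ny <- g$gy / mag
  (shiftReplicate(nx, 0L, 1L) - shiftReplicate(nx, 0L, -1L)) / 2 +
    (shiftReplicate(ny, 1L, 0L) - shiftReplicate(ny, -1L, 0L)) / 2
}

# zero-padded correlation of a matrix with a small binary/numeric kernel
# centered on each pixel; out-of-domain contributions are zero, matching the
# literal neighborhood sums in which only pixels of the image domain exist
zeroPadConv <- function(m, kernel) {
  r <- (nrow(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -r:r) {
    for (dc in -r:r) {
      kv <- kernel[dr + r + 1L, dc + r + 1L]
      if (kv == 0) next
      rs <- seq_len(nr) + dr
      cs <- seq_len(nc) + dc
      okr <- rs >= 1L & rs <= nr
      okc <- cs >= 1L & cs <= nc
      out[okr, okc] <- out[okr, okc] + kv * m[rs[okr], cs[okc]]
    }
  }
  out
}

asIntensityMatrix <- function(image) {
  if (is(image, "RetinalSample")) image <- intensities(image)
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix or a RetinalSample")
  image
}
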