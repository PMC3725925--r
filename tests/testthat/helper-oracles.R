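# Independent scalar-loop reference implementations. Everything here is
# written with explicit per-pixel for-loops and literal sums so it shares no
# code path with the vectorized package internals.

oracleCloseness <- function(radius, sigmaGSq) {
  w <- 2 * radius + 1
  h <- matrix(NA_real_, w, w)
  for (a in -radius:radius)
    for (b in -radius:radius)
      h[a + radius + 1, b + radius + 1] <- exp(-(a^2 + b^2) / (2 * sigmaGSq))
  h
}

oracleLambda <- function(radius, sigmaGSq, includeCenter = TRUE) {
  h <- oracleCloseness(radius, sigmaGSq)
  total <- 0
  for (a in -radius:radius)
    for (b in -radius:radius) {
      if (!includeCenter && a == 0 && b == 0) next
      total <- total + h[a + radius + 1, b + radius + 1]
    }
  lam <- matrix(0, 2 * radius + 1, 2 * radius + 1)
  for (a in -radius:radius)
    for (b in -radius:radius) {
      if (!includeCenter && a == 0 && b == 0) next
      lam[a + radius + 1, b + radius + 1] <-
        h[a + radius + 1, b + radius + 1] / total
    }
  lam
}

# count of pixels i whose window contains j, by brute double loop over i
oracleCount <- function(nr, nc, radius, includeCenter = TRUE) {
  cnt <- matrix(0, nr, nc)
  for (ir in 1:nr) for (ic in 1:nc)
    for (jr in max(1, ir - radius):min(nr, ir + radius))
      for (jc in max(1, ic - radius):min(nc, ic + radius)) {
        if (!includeCenter && jr == ir && jc == ic) next
        cnt[jr, jc] <- cnt[jr, jc] + 1
      }
  cnt
}

oracleEnergyDensity <- function(img, mu, radius, includeCenter = TRUE) {
  cnt <- oracleCount(nrow(img), ncol(img), radius, includeCenter)
  e <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    e[r, c] <- cnt[r, c] * (img[r, c] - mu)^2
  e
}

oracleH <- function(z, eps) 0.5 * (1 + (2 / pi) * atan(z / eps))
oracleD <- function(z, eps) (1 / pi) * eps / (eps^2 + z^2)

oracleDataEnergy <- function(img, phi, mu1, mu2, eps, radius,
                             includeCenter = TRUE) {
  e1 <- oracleEnergyDensity(img, mu1, radius, includeCenter)
  e2 <- oracleEnergyDensity(img, mu2, radius, includeCenter)
  total <- 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    H <- oracleH(phi[r, c], eps)
    total <- total + e1[r, c] * H + e2[r, c] * (1 - H)
  }
  total
}

# central differences with clamped (replicated) indices
oracleGradAt <- function(phi, r, c) {
  nr <- nrow(phi); nc <- ncol(phi)
  gy <- (phi[min(r + 1, nr), c] - phi[max(r - 1, 1), c]) / 2
  gx <- (phi[r, min(c + 1, nc)] - phi[r, max(c - 1, 1)]) / 2
  c(gx, gy)
}

oracleLengthEnergy <- function(phi, eps) {
  total <- 0
  for (r in seq_len(nrow(phi))) for (c in seq_len(ncol(phi))) {
    g <- oracleGradAt(phi, r, c)
    total <- total + oracleD(phi[r, c], eps) * sqrt(g[1]^2 + g[2]^2)
  }
  total
}

oracleDistRegEnergy <- function(phi) {
  total <- 0
  for (r in seq_len(nrow(phi))) for (c in seq_len(ncol(phi))) {
    g <- oracleGradAt(phi, r, c)
    total <- total + 0.5 * (sqrt(g[1]^2 + g[2]^2) - 1)^2
  }
  total
}

# literal double sum over pixels i and their neighborhoods
oracleUpdateMeans <- function(img, phi, eps, radius, includeCenter = TRUE,
                              hard = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  num1 <- den1 <- num2 <- den2 <- 0
  for (ir in 1:nr) for (ic in 1:nc)
    for (jr in max(1, ir - radius):min(nr, ir + radius))
      for (jc in max(1, ic - radius):min(nc, ic + radius)) {
        if (!includeCenter && jr == ir && jc == ic) next
        H <- if (hard) as.numeric(phi[jr, jc] >= 0)
             else oracleH(phi[jr, jc], eps)
        num1 <- num1 + img[jr, jc] * H
        den1 <- den1 + H
        num2 <- num2 + img[jr, jc] * (1 - H)
        den2 <- den2 + (1 - H)
      }
  c(if (den1 > 1e-12) num1 / den1 else NA_real_,
    if (den2 > 1e-12) num2 / den2 else NA_real_)
}

oracleCurvatureField <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  nx <- ny <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    g <- oracleGradAt(phi, r, c)
    mag <- max(sqrt(g[1]^2 + g[2]^2), 1e-10)
    nx[r, c] <- g[1] / mag
    ny[r, c] <- g[2] / mag
  }
  k <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    k[r, c] <- (nx[r, min(c + 1, nc)] - nx[r, max(c - 1, 1)]) / 2 +
               (ny[min(r + 1, nr), c] - ny[max(r - 1, 1), c]) / 2
  }
  k
}

oracleLaplacianField <- function(phi) {
  nr <- nrow(phi); nc <- ncol(phi)
  l <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    l[r, c] <- phi[min(r + 1, nr), c] + phi[max(r - 1, 1), c] +
               phi[r, min(c + 1, nc)] + phi[r, max(c - 1, 1)] - 4 * phi[r, c]
  l
}

# one full flow iteration mirroring the stabilized scheme, in loops
oracleFlowStep <- function(img, phi, mu1, mu2, alpha, beta, dt, eps, radius,
                           includeCenter = TRUE, capData = 5, capReg = 2) {
  nr <- nrow(img); nc <- ncol(img)
  e1 <- oracleEnergyDensity(img, mu1, radius, includeCenter)
  e2 <- oracleEnergyDensity(img, mu2, radius, includeCenter)
  k <- oracleCurvatureField(phi)
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    dl <- oracleD(phi[r, c], eps)
    f <- dt * (dl * (e2[r, c] - e1[r, c]) + alpha * dl * k[r, c])
    out[r, c] <- phi[r, c] + min(max(f, -capData), capData)
  }
  if (beta > 0) {
    m <- max(1, ceiling(8 * beta * dt))
    tau <- dt / m
    cap <- capReg / m
    for (s in seq_len(m)) {
      lapF <- oracleLaplacianField(out)
      kF <- oracleCurvatureField(out)
      nxt <- out
      for (r in 1:nr) for (c in 1:nc) {
        u <- tau * beta * (lapF[r, c] - kF[r, c])
        nxt[r, c] <- out[r, c] + min(max(u, -cap), cap)
      }
      out <- nxt
    }
  }
  out
}
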