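# Independent brute-force oracles for the texture-matrix features.
# Everything here is written with plain loops straight from the textbook
# definitions and shares no code with the package implementation.

oracle_offsets13 <- function() {
  offs <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      offs[[length(offs) + 1]] <- c(dx, dy, dz)
  }
  offs
}

random_level_volume <- function(dims, Ng, p_mask = 0.9, seed = 1) {
  withr::with_seed(seed, {
    lev <- array(sample.int(Ng, prod(dims), replace = TRUE), dims)
    lev[runif(prod(dims)) > p_mask] <- 0L
    if (!any(lev > 0L)) lev[1] <- 1L
    lev
  })
}

as_dz <- function(lev) {
  structure(list(levels = lev, bin_width_hu = 1, anchor_hu = 0,
                 Ng = max(lev), mask = lev > 0L),
            class = "discretized_volume")
}

# ---- GLCM ----

oracle_glcm_counts <- function(lev, Ng, off) {
  d <- dim(lev)
  m <- matrix(0, Ng, Ng)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
    b <- lev[x2, y2, z2]
    if (b == 0) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  vx <- 0; vy <- 0
  for (i in 1:Ng) { vx <- vx + (i - mux)^2 * px[i]; vy <- vy + (i - muy)^2 * py[i] }
  psum <- rep(0, 2 * Ng); pdif <- rep(0, Ng)
  jmax <- 0; javg <- 0; hxy <- 0; asm <- 0; contrast <- 0; dissim <- 0
  hom <- 0; hom_n <- 0; idm <- 0; idm_n <- 0; invvar <- 0; autoc <- 0
  ct <- 0; cs <- 0; cp <- 0; hxy1 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
    if (p > jmax) jmax <- p
    javg <- javg + i * p
    if (p > 0) hxy <- hxy - p * log2(p)
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    dissim <- dissim + abs(i - j) * p
    hom <- hom + p / (1 + abs(i - j))
    hom_n <- hom_n + p / (1 + abs(i - j) / Ng)
    idm <- idm + p / (1 + (i - j)^2)
    idm_n <- idm_n + p / (1 + (i - j)^2 / Ng^2)
    if (i != j) invvar <- invvar + p / (i - j)^2
    autoc <- autoc + i * j * p
    ct <- ct + (i + j - mux - muy)^2 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    cp <- cp + (i + j - mux - muy)^4 * p
    if (p > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - p * log2(px[i] * py[j])
  }
  jvar <- 0
  for (i in 1:Ng) for (j in 1:Ng) jvar <- jvar + (i - javg)^2 * P[i, j]
  sa <- 0; for (k in 2:(2 * Ng)) sa <- sa + k * psum[k]
  sv <- 0; se <- 0
  for (k in 2:(2 * Ng)) {
    sv <- sv + (k - sa)^2 * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  }
  da <- 0; for (k in 0:(Ng - 1)) da <- da + k * pdif[k + 1]
  dv <- 0; de <- 0
  for (k in 0:(Ng - 1)) {
    dv <- dv + (k - da)^2 * pdif[k + 1]
    if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * log2(pdif[k + 1])
  }
  hx <- 0; for (i in 1:Ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hy <- 0; for (j in 1:Ng) if (py[j] > 0) hy <- hy - py[j] * log2(py[j])
  hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng)
    if (px[i] * py[j] > 0) hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  corr <- if (vx > 1e-12 && vy > 1e-12) (autoc - mux * muy) / sqrt(vx * vy) else 0
  # MCC via explicit Q construction
  keep <- which(px > 0); keepj <- which(py > 0)
  mcc <- if (length(keep) < 2 || length(keepj) < 2) 1 else {
    Q <- matrix(0, length(keep), length(keep))
    for (a in seq_along(keep)) for (b in seq_along(keep)) {
      s <- 0
      for (k in keepj)
        s <- s + P[keep[a], k] * P[keep[b], k] / (px[keep[a]] * py[k])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(ev[2], 1)))
  }
  c(jointMax = jmax, jointAverage = javg, jointVariance = jvar,
    jointEntropy = hxy, sumAverage = sa, sumVariance = sv, sumEntropy = se,
    diffAverage = da, diffVariance = dv, diffEntropy = de, jointEnergy = asm,
    contrast = contrast, dissimilarity = dissim, homogenity = hom,
    homogenity_n = hom_n, idm = idm, idm_n = idm_n, inverseVariance = invvar,
    correlation = corr, autocorrelation = autoc, clusterTendency = ct,
    clusterShade = cs, clusterProminence = cp, imc1 = imc1, imc2 = imc2,
    mcc = mcc)
}

# ---- NGTDM ----

oracle_ngtdm_features <- function(lev, Ng) {
  d <- dim(lev)
  s <- rep(0, Ng); n <- rep(0, Ng); N <- 0
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    tot <- 0; cnt <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      b <- lev[x2, y2, z2]
      if (b > 0) { tot <- tot + b; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    N <- N + 1
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - tot / cnt)
  }
  if (N == 0)
    return(c(coarseness = 0, neighContrast = 0, busyness = 0,
             complexity = 0, strength = 0))
  p <- n / N
  eps <- 1e-12
  pres <- which(p > 0)
  coars <- if (sum(p * s) > eps) 1 / sum(p * s) else 1 / eps
  contr <- 0
  if (length(pres) > 1) {
    acc <- 0
    for (i in pres) for (j in pres) acc <- acc + p[i] * p[j] * (i - j)^2
    contr <- acc / (length(pres) * (length(pres) - 1)) * sum(s) / N
  }
  bd <- 0
  for (i in pres) for (j in pres) bd <- bd + abs(i * p[i] - j * p[j])
  busy <- if (bd > eps) sum(p * s) / bd else 0
  comp <- 0
  for (i in pres) for (j in pres)
    comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  comp <- comp / N
  stg <- 0
  for (i in pres) for (j in pres) stg <- stg + (p[i] + p[j]) * (i - j)^2
  stg <- if (sum(s) > eps) stg / sum(s) else 0
  c(coarseness = coars, neighContrast = contr, busyness = busy,
    complexity = comp, strength = stg)
}

# ---- GLRLM ----

oracle_glrlm_runs <- function(lev, off) {
  d <- dim(lev)
  runs <- matrix(numeric(0), 0, 2)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    # run start: predecessor along -off missing, out of mask or different
    xp <- x - off[1]; yp <- y - off[2]; zp <- z - off[3]
    pred_same <- xp >= 1 && xp <= d[1] && yp >= 1 && yp <= d[2] &&
      zp >= 1 && zp <= d[3] && lev[xp, yp, zp] == a
    if (pred_same) next
    len <- 1
    xc <- x + off[1]; yc <- y + off[2]; zc <- z + off[3]
    while (xc >= 1 && xc <= d[1] && yc >= 1 && yc <= d[2] &&
           zc >= 1 && zc <= d[3] && lev[xc, yc, zc] == a) {
      len <- len + 1
      xc <- xc + off[1]; yc <- yc + off[2]; zc <- zc + off[3]
    }
    runs <- rbind(runs, c(a, len))
  }
  runs
}

oracle_glrlm_features <- function(runs, Ng, Np) {
  nms <- c("shortRunEmph", "longRunEmph", "grayLevelNonUnif",
           "grayLevelNonUnif_n", "runLengthNonUnif", "runLengthNonUnif_n",
           "runPercentage", "lowGrayRunEmph", "highGrayRunEmph",
           "shortRunLowGrayEmph", "shortRunHighGrayEmph",
           "longRunLowGrayEmph", "longRunHighGrayEmph", "grayLevelVar",
           "runLengthVar", "runEntropy")
  if (nrow(runs) == 0) return(setNames(rep(0, 16), nms))
  Nr <- nrow(runs)
  Lmax <- max(runs[, 2])
  R <- matrix(0, Ng, Lmax)
  for (r in 1:Nr) R[runs[r, 1], runs[r, 2]] <- R[runs[r, 1], runs[r, 2]] + 1
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0
  lrh <- 0; mu_i <- 0; mu_l <- 0; ent <- 0
  for (i in 1:Ng) for (l in 1:Lmax) {
    cnt <- R[i, l]
    if (cnt == 0) next
    sre <- sre + cnt / l^2; lre <- lre + cnt * l^2
    lgl <- lgl + cnt / i^2; hgl <- hgl + cnt * i^2
    srl <- srl + cnt / (i^2 * l^2); srh <- srh + cnt * i^2 / l^2
    lrl <- lrl + cnt * l^2 / i^2; lrh <- lrh + cnt * i^2 * l^2
    mu_i <- mu_i + cnt * i / Nr; mu_l <- mu_l + cnt * l / Nr
    ent <- ent - (cnt / Nr) * log2(cnt / Nr)
  }
  glv <- 0; rlv <- 0
  for (i in 1:Ng) for (l in 1:Lmax) {
    cnt <- R[i, l]
    if (cnt == 0) next
    glv <- glv + cnt / Nr * (i - mu_i)^2
    rlv <- rlv + cnt / Nr * (l - mu_l)^2
  }
  gln <- sum(rowSums(R)^2); rln <- sum(colSums(R)^2)
  setNames(c(sre / Nr, lre / Nr, gln / Nr, gln / Nr^2, rln / Nr, rln / Nr^2,
             Nr / Np, lgl / Nr, hgl / Nr, srl / Nr, srh / Nr, lrl / Nr,
             lrh / Nr, glv, rlv, ent), nms)
}

# ---- GLSZM ----

oracle_glszm_zones <- function(lev) {
  d <- dim(lev)
  visited <- array(FALSE, d)
  zones <- matrix(numeric(0), 0, 2)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0 || visited[x, y, z]) next
    # stack flood fill over 26-neighbors of equal level
    stack <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        x2 <- v[1] + dx; y2 <- v[2] + dy; z2 <- v[3] + dz
        if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] ||
            z2 < 1 || z2 > d[3]) next
        if (!visited[x2, y2, z2] && lev[x2, y2, z2] == a) {
          visited[x2, y2, z2] <- TRUE
          stack[[length(stack) + 1]] <- c(x2, y2, z2)
        }
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  zones
}

oracle_glszm_features <- function(zones, Ng, Np) {
  nms <- c("smallZoneEmph", "largeZoneEmph", "grayLevelNonUnifZ",
           "grayLevelNonUnifZ_n", "sizeZoneNonUnif", "sizeZoneNonUnif_n",
           "zonePercentage", "grayLevelVarZ", "sizeVar", "sizeVar_n",
           "lowGrayZoneEmph", "highGrayZoneEmph", "smallZoneLowGrayEmph",
           "smallZoneHighGrayEmph", "largeZoneLowGrayEmph",
           "largeZoneHighGrayEmph")
  if (nrow(zones) == 0) return(setNames(rep(0, 16), nms))
  Nz <- nrow(zones)
  i <- zones[, 1]; s <- zones[, 2]
  gln <- 0
  for (g in 1:Ng) gln <- gln + sum(i == g)^2
  szn <- 0
  for (sz in unique(s)) szn <- szn + sum(s == sz)^2
  mu_i <- mean(i); mu_s <- mean(s)
  setNames(c(mean(1 / s^2), mean(s^2), gln / Nz, gln / Nz^2, szn / Nz,
             szn / Nz^2, Nz / Np, mean((i - mu_i)^2), mean((s - mu_s)^2),
             mean((s - mu_s)^2) / mu_s^2, mean(1 / i^2), mean(i^2),
             mean(1 / (i^2 * s^2)), mean(i^2 / s^2), mean(s^2 / i^2),
             mean(i^2 * s^2)), nms)
}
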