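# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive re-derivations (exhaustive search, fixpoint iteration,
# closed-form textbook formulas) kept separate from the package's
# implementations.

# Exhaustive three-class Otsu on integer-valued data 0..(n_bins-1), one
# value per bin. Returns the split pair (i, j): classes {v <= i},
# {i < v <= j}, {v > j}; ties broken by smallest (i, j).
oracle_otsu2_splits <- function(values, n_bins) {
  mu <- mean(values)
  best <- -Inf
  bi <- bj <- NA
  for (i in 0:(n_bins - 3)) {
    for (j in (i + 1):(n_bins - 2)) {
      ssb <- 0
      for (cls in list(values[values <= i],
                       values[values > i & values <= j],
                       values[values > j])) {
        if (length(cls) > 0)
          ssb <- ssb + length(cls) * (mean(cls) - mu)^2
      }
      if (ssb > best + 1e-9) {
        best <- ssb
        bi <- i
        bj <- j
      }
    }
  }
  c(bi, bj)
}

# Exhaustive two-class Otsu on integer-valued data; returns split value k
# (classes {v <= k} vs {v > k}), smallest k on ties.
oracle_otsu1_split <- function(values, n_bins) {
  mu <- mean(values)
  best <- -Inf
  bk <- NA
  for (k in 0:(n_bins - 2)) {
    lo <- values[values <= k]
    hi <- values[values > k]
    ssb <- 0
    if (length(lo)) ssb <- ssb + length(lo) * (mean(lo) - mu)^2
    if (length(hi)) ssb <- ssb + length(hi) * (mean(hi) - mu)^2
    if (ssb > best + 1e-9) {
      best <- ssb
      bk <- k
    }
  }
  bk
}

# 26-neighbourhood grayscale dilation (max filter), small volumes only.
r_dilate26 <- function(v) {
  d <- dim(v)
  out <- v
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sz <- seq_len(d[1]) + dz
    sy <- seq_len(d[2]) + dy
    sx <- seq_len(d[3]) + dx
    okz <- sz >= 1 & sz <= d[1]
    oky <- sy >= 1 & sy <= d[2]
    okx <- sx >= 1 & sx <= d[3]
    shifted <- array(-Inf, d)
    shifted[okz, oky, okx] <- v[sz[okz], sy[oky], sx[okx]]
    out <- pmax(out, shifted)
  }
  out
}

# Grayscale reconstruction by dilation: iterate geodesic dilation to the
# fixpoint.
r_reconstruct <- function(marker, mask) {
  rec <- pmin(marker, mask)
  repeat {
    nxt <- pmin(r_dilate26(rec), mask)
    if (isTRUE(all.equal(nxt, rec, tolerance = 0))) return(rec)
    rec <- nxt
  }
}

# Regional maxima by plateau flood fill: an equal-valued 26-connected
# plateau with no greater neighbour and at least one lower neighbour.
r_regional_maxima <- function(v) {
  d <- dim(v)
  n <- prod(d)
  seen <- logical(n)
  out <- logical(n)
  coords <- arrayInd(seq_len(n), d)
  neighbours <- function(i) {
    co <- coords[i, ]
    res <- integer(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      z <- co[1] + dz; y <- co[2] + dy; x <- co[3] + dx
      if (z >= 1 && z <= d[1] && y >= 1 && y <= d[2] && x >= 1 && x <= d[3])
        res <- c(res, z + d[1] * (y - 1) + d[1] * d[2] * (x - 1))
    }
    res
  }
  for (i0 in seq_len(n)) {
    if (seen[i0]) next
    val <- v[i0]
    plateau <- i0
    seen[i0] <- TRUE
    queue <- i0
    has_higher <- FALSE
    has_lower <- FALSE
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      for (j in neighbours(i)) {
        if (v[j] > val) has_higher <- TRUE
        else if (v[j] < val) has_lower <- TRUE
        else if (!seen[j]) {
          seen[j] <- TRUE
          plateau <- c(plateau, j)
          queue <- c(queue, j)
        }
      }
    }
    if (!has_higher && has_lower) out[plateau] <- TRUE
  }
  array(out, d)
}

r_extended_maxima_mask <- function(v, h) {
  r_regional_maxima(r_reconstruct(v - h, v))
}

# Closed-form pooled-variance two-sample t test.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Long-hand one-way ANOVA table.
oracle_anova_f <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

# Gaussian spot field builder: spots of given amplitude/SD rendered
# in-plane at (z, y, x) voxel positions (0-based), zero background.
spot_volume <- function(dims, spots, amplitude = 200, sigma = 1) {
  v <- array(0, dims)
  if (nrow(spots) == 0) return(v)
  for (s in seq_len(nrow(spots))) {
    gy <- exp(-((seq_len(dims[2]) - 1 - spots$y[s])^2) / (2 * sigma^2))
    gx <- exp(-((seq_len(dims[3]) - 1 - spots$x[s])^2) / (2 * sigma^2))
    z <- spots$z[s] + 1
    v[z, , ] <- v[z, , ] + amplitude * outer(gy, gx)
  }
  v
}
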