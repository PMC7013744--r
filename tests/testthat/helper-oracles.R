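# Independent brute-force re-implementations of every texture family,
# written as naive per-pixel loops directly from the definitions.  They
# share no code with the package implementations.

oracle_offset <- function(angle, d = 1) {
  list("0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
       "135" = c(-d, -d))[[as.character(angle)]]
}

oracle_entropy <- function(p) {
  e <- 0
  for (v in p) if (v > 0) e <- e - v * log2(v)
  e
}

oracle_histogram <- function(block) {
  v <- as.numeric(block)
  n <- length(v)
  vals <- sort(unique(v))
  p <- vapply(vals, function(g) sum(v == g) / n, numeric(1))
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  sdev <- sqrt(m2)
  c(sum(p^2), oracle_entropy(p),
    if (sdev > 0) m4 / sdev^4 else 0,
    mu,
    if (sdev > 0) m3 / sdev^3 else 0,
    sdev, m2)
}

oracle_glcm_one <- function(q, levels, angle, d) {
  off <- oracle_offset(angle, d)
  C <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        C[q[r, cc] + 1, q[r2, c2] + 1] <- C[q[r, cc] + 1, q[r2, c2] + 1] + 1
        C[q[r2, c2] + 1, q[r, cc] + 1] <- C[q[r2, c2] + 1, q[r, cc] + 1] + 1
      }
    }
  }
  P <- C / sum(C)
  g <- 0:(levels - 1)
  mux <- 0
  for (i in g) mux <- mux + i * sum(P[i + 1, ])
  varx <- 0
  for (i in g) varx <- varx + (i - mux)^2 * sum(P[i + 1, ])
  p_sum <- numeric(2 * levels - 1)
  p_dif <- numeric(levels)
  for (i in g) for (j in g) {
    p_sum[i + j + 1] <- p_sum[i + j + 1] + P[i + 1, j + 1]
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + P[i + 1, j + 1]
  }
  sum_avg <- sum((0:(2 * levels - 2)) * p_sum)
  dif_avg <- sum((0:(levels - 1)) * p_dif)
  corr <- 0; sos <- 0; sv <- 0; dv <- 0; contrast <- 0; hom <- 0
  shade <- 0; prom <- 0
  for (i in g) for (j in g) {
    p <- P[i + 1, j + 1]
    corr <- corr + i * j * p
    sos <- sos + (i - mux)^2 * p
    contrast <- contrast + (i - j)^2 * p
    hom <- hom + p / (1 + (i - j)^2)
    shade <- shade + (i + j - 2 * mux)^3 * p
    prom <- prom + (i + j - 2 * mux)^4 * p
  }
  for (k in 0:(2 * levels - 2)) sv <- sv + (k - sum_avg)^2 * p_sum[k + 1]
  for (k in 0:(levels - 1)) dv <- dv + (k - dif_avg)^2 * p_dif[k + 1]
  corr <- if (sqrt(varx) > 1e-12) (corr - mux^2) / varx else 0
  c(corr, oracle_entropy(p_dif), dv, sum_avg, oracle_entropy(p_sum),
    sos, sv, contrast, sum(P^2), oracle_entropy(as.vector(P)), hom,
    shade, prom)
}

oracle_glcm <- function(q, levels, angles = c(0, 45, 90, 135), d = 1) {
  rowMeans(vapply(angles, function(a) oracle_glcm_one(q, levels, a, d),
                  numeric(13)))
}

oracle_sfm <- function(q, angles = c(0, 45, 90, 135), d = 1) {
  per <- vapply(angles, function(ang) {
    off <- oracle_offset(ang, d)
    tot <- 0; cnt <- 0
    for (r in seq_len(nrow(q))) {
      for (cc in seq_len(ncol(q))) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
          tot <- tot + abs(q[r, cc] - q[r2, c2])
          cnt <- cnt + 1
        }
      }
    }
    tot / cnt
  }, numeric(1))
  mean(per)
}

# Runs found by walking each direction from pixels with no predecessor.
oracle_glrlm_one <- function(q, levels, angle) {
  off <- oracle_offset(angle, 1)
  runs <- list()
  inside <- function(r, cc) r >= 1 && r <= nrow(q) && cc >= 1 && cc <= ncol(q)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      if (inside(r - off[1], cc - off[2])) next  # not a line start
      rr <- r; c2 <- cc
      len <- 1; val <- q[rr, c2]
      repeat {
        nr <- rr + off[1]; nc <- c2 + off[2]
        if (!inside(nr, nc)) { runs[[length(runs) + 1]] <- c(val, len); break }
        if (q[nr, nc] == val) {
          len <- len + 1
        } else {
          runs[[length(runs) + 1]] <- c(val, len)
          val <- q[nr, nc]; len <- 1
        }
        rr <- nr; c2 <- nc
      }
    }
  }
  m <- do.call(rbind, runs)
  n_runs <- nrow(m)
  sre <- sum(1 / m[, 2]^2) / n_runs
  lre <- sum(m[, 2]^2) / n_runs
  gln <- sum(vapply(0:(levels - 1), function(g) sum(m[, 1] == g)^2,
                    numeric(1))) / n_runs
  rln <- sum(vapply(seq_len(max(m[, 2])), function(l) sum(m[, 2] == l)^2,
                    numeric(1))) / n_runs
  c(sre, lre, gln, rln, n_runs / length(q))
}

oracle_glrlm <- function(q, levels, directions = c(0, 45, 90, 135)) {
  rowMeans(vapply(directions, function(a) oracle_glrlm_one(q, levels, a),
                  numeric(5)))
}

# Per-pixel 2-D convolution (kernel flipped) restricted to the valid area.
oracle_conv2 <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  out <- matrix(0, nrow(x) - kr + 1, ncol(x) - kc + 1)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      acc <- 0
      for (a in seq_len(kr)) {
        for (b in seq_len(kc)) {
          acc <- acc + k[a, b] * x[i + kr - a, j + kc - b]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_laws <- function(block, vectors) {
  combos <- c("LE", "EL", "SL", "EE", "LS")
  out <- numeric(0)
  vars <- numeric(0)
  for (nm in combos) {
    u <- vectors[[substr(nm, 1, 1)]]
    v <- vectors[[substr(nm, 2, 2)]]
    r <- abs(oracle_conv2(block, outer(u, v)))
    out <- c(out, mean(r))
    vars <- c(vars, sum((r - mean(r))^2) / length(r))
  }
  c(out, vars)
}

oracle_ngldm <- function(q, d = 1, a = 0) {
  nr <- nrow(q); nc <- ncol(q)
  recs <- list()
  for (r in (1 + d):(nr - d)) {
    for (cc in (1 + d):(nc - d)) {
      k <- 0
      for (dr in -d:d) for (dc in -d:d) {
        if (dr == 0 && dc == 0) next
        if (abs(q[r + dr, cc + dc] - q[r, cc]) <= a) k <- k + 1
      }
      recs[[length(recs) + 1]] <- c(q[r, cc], k)
    }
  }
  m <- do.call(rbind, recs)
  keys <- paste(m[, 1], m[, 2])
  qc <- table(keys)
  n <- sum(qc)
  kv <- as.numeric(vapply(strsplit(names(qc), " "), `[`, character(1), 2))
  qn <- as.numeric(qc)
  sne <- sum(ifelse(kv >= 1, qn / kv^2, 0)) / n
  lne <- sum(qn * kv^2) / n
  per_k <- tapply(qn, kv, sum)
  nnu <- sum(per_k^2) / n
  sm <- sum(qn^2) / n
  c(sne, lne, nnu, sm, oracle_entropy(qn / n))
}

oracle_ngtdm <- function(q, d = 1, epsilon = 1e-6) {
  nr <- nrow(q); nc <- ncol(q)
  lv <- integer(0); dif <- numeric(0)
  for (r in (1 + d):(nr - d)) {
    for (cc in (1 + d):(nc - d)) {
      tot <- 0; cnt <- 0
      for (dr in -d:d) for (dc in -d:d) {
        if (dr == 0 && dc == 0) next
        tot <- tot + q[r + dr, cc + dc]; cnt <- cnt + 1
      }
      lv <- c(lv, q[r, cc])
      dif <- c(dif, abs(q[r, cc] - tot / cnt))
    }
  }
  gi <- sort(unique(lv))
  s <- vapply(gi, function(g) sum(dif[lv == g]), numeric(1))
  n <- length(lv)
  p <- vapply(gi, function(g) sum(lv == g) / n, numeric(1))
  ng <- length(gi)
  busy_den <- 0; contrast1 <- 0; complexity <- 0; strength_num <- 0
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      busy_den <- busy_den + abs(gi[i] * p[i] - gi[j] * p[j])
      contrast1 <- contrast1 + p[i] * p[j] * (gi[i] - gi[j])^2
      complexity <- complexity + abs(gi[i] - gi[j]) *
        (p[i] * s[i] + p[j] * s[j]) / (n * (p[i] + p[j]))
      strength_num <- strength_num + (p[i] + p[j]) * (gi[i] - gi[j])^2
    }
  }
  c(
    sum(p * s) / max(busy_den, epsilon),
    1 / (epsilon + sum(p * s)),
    complexity,
    if (ng > 1) contrast1 / (ng * (ng - 1)) * sum(s) / n else 0,
    strength_num / (epsilon + sum(s))
  )
}

oracle_wavelet_ll <- function(x) {
  n <- nrow(x); m <- ncol(x)
  xr <- if (n %% 2 == 1) rbind(x, x[n, , drop = FALSE]) else x
  xr <- if (m %% 2 == 1) cbind(xr, xr[, m, drop = FALSE]) else xr
  out <- matrix(0, nrow(xr) / 2, ncol(xr) / 2)
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- (xr[2 * i - 1, 2 * j - 1] + xr[2 * i, 2 * j - 1] +
                      xr[2 * i - 1, 2 * j] + xr[2 * i, 2 * j]) / 2
    }
  }
  out
}

oracle_fourier <- function(block) {
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1), c(0, -1), c(-1, -1),
               c(-1, 0), c(-1, 1))
  nr <- nrow(block); nc <- ncol(block)
  mags <- NULL; phs <- NULL
  for (r in 2:(nr - 1)) {
    for (cc in 2:(nc - 1)) {
      xs <- vapply(offs, function(o) block[r + o[1], cc + o[2]], numeric(1))
      mg <- numeric(8); ph <- numeric(8)
      for (u in 0:7) {
        re <- 0; im <- 0
        for (n in 0:7) {
          re <- re + xs[n + 1] * cos(2 * pi * u * n / 8)
          im <- im - xs[n + 1] * sin(2 * pi * u * n / 8)
        }
        if (abs(re) < 1e-8) re <- 0
        if (abs(im) < 1e-8) im <- 0
        mg[u + 1] <- sqrt(re^2 + im^2)
        ph[u + 1] <- if (mg[u + 1] == 0) 0 else atan2(im, re)
      }
      mags <- rbind(mags, mg); phs <- rbind(phs, ph)
    }
  }
  popsd <- function(col) sqrt(sum((col - mean(col))^2) / length(col))
  c(colMeans(mags), colMeans(phs), apply(mags, 2, popsd),
    apply(phs, 2, popsd))
}
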