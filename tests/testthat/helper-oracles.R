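# Independent oracles, deliberately implemented with different algorithms
# than the package (stack-based flood fill in plain R, direct-definition
# texture matrices, pattern-count Euler characteristic).

# Connected-component count of TRUE cells, stack-based flood fill.
oracle_label_count <- function(img, conn8) {
  nr <- nrow(img); nc <- ncol(img)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (conn8) {
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  } else {
    cbind(c(-1,1,0,0), c(0,0,-1,1))
  }
  count <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!img[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc && img[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Betti pair by flood fill: b0 = 8-connected foreground components; b1 =
# 4-connected components of the zero-padded background minus the outer one.
oracle_betti <- function(img) {
  img <- as.matrix(img) & TRUE
  b0 <- oracle_label_count(img, conn8 = TRUE)
  pad <- matrix(FALSE, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  b1 <- oracle_label_count(!pad, conn8 = FALSE) - 1L
  c(b0 = b0, b1 = b1)
}

# Euler characteristic under 8-connectivity by 2x2 quad pattern counting
# (Gray): chi = (Q1 - Q3 - 2 * Qd) / 4 over all 2x2 windows of the
# zero-padded image, where Q1/Q3 count quads with exactly one/three
# foreground pixels and Qd the two diagonal patterns.
oracle_euler8 <- function(img) {
  pad <- matrix(FALSE, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  q1 <- q3 <- qd <- 0L
  for (r in 1:(nrow(pad) - 1)) for (c in 1:(ncol(pad) - 1)) {
    quad <- pad[r:(r + 1), c:(c + 1)]
    s <- sum(quad)
    if (s == 1) q1 <- q1 + 1L
    if (s == 3) q3 <- q3 + 1L
    if (s == 2 && quad[1, 1] == quad[2, 2] && quad[1, 2] == quad[2, 1] &&
        quad[1, 1] != quad[1, 2]) qd <- qd + 1L
  }
  (q1 - q3 - 2L * qd) / 4
}

# 3-D 6-connected component count (for mask-topology checks).
oracle_label3d_count <- function(arr) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  count <- 0L
  offs <- rbind(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))
  idx_all <- which(arr & !seen)
  while (length(idx_all <- which(arr & !seen)) > 0) {
    count <- count + 1L
    stack <- idx_all[1]
    seen[stack] <- TRUE
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      z <- (i - 1) %/% (d[1] * d[2]) + 1
      rem <- (i - 1) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1
      x <- rem %% d[1] + 1
      for (k in 1:6) {
        p <- c(x, y, z) + offs[k, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (arr[j] && !seen[j]) { seen[j] <- TRUE; stack <- c(stack, j) }
      }
    }
  }
  count
}

# Direct-definition symmetric GLCM counts for one direction (dr, dc),
# levels 1..G, 0 = outside ROI.
oracle_glcm_counts <- function(lev, G, dr, dc) {
  M <- matrix(0, G, G)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a <- lev[r, c]
    if (a == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    b <- lev[r2, c2]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# Direct run enumeration for one direction given as a unit step (dr, dc).
oracle_runs <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  runs <- list()
  starts <- which(matrix(TRUE, nr, nc), arr.ind = TRUE)
  is_start <- function(r, c) {
    pr <- r - dr; pc <- c - dc
    pr < 1 || pr > nr || pc < 1 || pc > nc
  }
  for (k in seq_len(nrow(starts))) {
    r <- starts[k, 1]; c <- starts[k, 2]
    if (!is_start(r, c)) next
    cur <- 0; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lev[r, c]
      if (v == cur && v != 0) len <- len + 1
      else {
        if (cur != 0) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- v; len <- if (v != 0) 1 else 0
      }
      r <- r + dr; c <- c + dc
    }
    if (cur != 0) runs[[length(runs) + 1]] <- c(cur, len)
  }
  if (length(runs) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, runs)
}

# Zones (level, size) by per-level 8-connected labeling.
oracle_zones <- function(lev) {
  out <- list()
  for (v in sort(unique(lev[lev > 0]))) {
    bin <- lev == v
    nr <- nrow(bin); nc <- ncol(bin)
    seen <- matrix(FALSE, nr, nc)
    for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
      if (!bin[r0, c0] || seen[r0, c0]) next
      size <- 0
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc && bin[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
      out[[length(out) + 1]] <- c(v, size)
    }
  }
  do.call(rbind, out)
}

# NGTDM accumulators by direct neighbourhood scan.
oracle_ngtdm <- function(lev, G) {
  n <- integer(G); s <- numeric(G)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    v <- lev[r, c]
    if (v == 0) next
    vals <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (lev[r2, c2] > 0) vals <- c(vals, lev[r2, c2])
    }
    if (length(vals) == 0) next
    n[v] <- n[v] + 1L
    s[v] <- s[v] + abs(v - mean(vals))
  }
  list(n = n, s = s)
}

# Direct 1-D correlation with half-point symmetric extension (wavelet oracle).
oracle_swt1d <- function(x, h, off = 2) {
  n <- length(x)
  refl <- function(i) {
    while (i < 0 || i >= n) {
      if (i < 0) i <- -1 - i
      if (i >= n) i <- 2 * n - 1 - i
    }
    i
  }
  vapply(seq_len(n) - 1, function(i) {
    sum(vapply(seq_along(h), function(k) h[k] * x[refl(i + k - 1 - off) + 1],
               numeric(1)))
  }, numeric(1))
}

random_binary <- function(nr, nc, p = 0.5) matrix(runif(nr * nc) < p, nr, nc)

# Minimal quantized slice for texture tests.
make_qslice <- function(image, roi = NULL, bits = 5L) {
  image <- as.matrix(image)
  storage.mode(image) <- "integer"
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  structure(list(image = image, roi = roi, pixel_size = 0.77, bits = bits),
            class = "quantized_slice")
}
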