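# Independent oracles used across the suite. These re-derive results from
# first principles (literal loops, closed forms, generic solvers) and must
# stay independent of the package's computational paths.

# literal non-local means: double loop over pixels and search window,
# Gaussian-weighted mean squared patch distance on a mirror-padded image,
# single normalisation, self-weight = max of the other weights
nlm_oracle <- function(img, patch_r, search_r, kernel_sd, h, h1, h2,
                       scheme = c("original", "improved")) {
  scheme <- match.arg(scheme)
  nr <- nrow(img)
  nc <- ncol(img)
  mirror <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n - i + 1, i)
  }
  offs <- seq(-patch_r, patch_r)
  g <- outer(offs, offs, function(a, b) {
    exp(-(a^2 + b^2) / (2 * kernel_sd^2))
  })
  g <- g / sum(g)
  patch <- function(i, j) {
    img[cbind(
      mirror(rep(i + offs, times = length(offs)), nr),
      mirror(rep(j + offs, each = length(offs)), nc)
    )]
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      pi_ <- patch(i, j)
      rs <- max(1, i - search_r):min(nr, i + search_r)
      cs <- max(1, j - search_r):min(nc, j + search_r)
      ws <- c()
      vs <- c()
      for (r in rs) {
        for (cc in cs) {
          if (r == i && cc == j) next
          D <- sum(g * (pi_ - patch(r, cc))^2)
          w <- if (scheme == "original") {
            exp(-D / h^2)
          } else if (D <= h2) {
            exp(-D / h1^2) * cos(pi * D / (2 * h2))
          } else {
            0
          }
          ws <- c(ws, w)
          vs <- c(vs, img[r, cc])
        }
      }
      wself <- if (max(ws) > 0) max(ws) else 1
      ws <- c(ws, wself)
      vs <- c(vs, img[i, j])
      wn <- ws / sum(ws)
      stopifnot(abs(sum(wn) - 1) < 1e-9)
      out[i, j] <- sum(wn * vs)
    }
  }
  out
}

# generic 2x2 linear solve of the two-contact equilibrium in (N1, N2)
force_balance_oracle <- function(F, theta, alpha, mu) {
  cpa <- mu * cos(alpha) - sin(alpha)
  cva <- mu * sin(alpha) + cos(alpha)
  A <- rbind(c(cpa, -cpa), c(cva, cva))
  b <- c(F * sin(theta), F * cos(theta))
  n <- solve(A, b)
  list(N1 = n[1], N2 = n[2])
}

# closed-form force ratio k = N1/N2 from the printed tangent expression
k_closed_form <- function(theta, alpha, mu) {
  ta <- tan(alpha)
  tt <- tan(theta)
  (ta - mu - mu * ta * tt - tt) / (ta - mu + mu * ta * tt + tt)
}

# brute-force directional non-maximum suppression with the package's
# plateau rule (>= forward, > backward), borders excluded
nms_oracle <- function(modulus, bins) {
  offs <- list(`0` = c(0, 1), `45` = c(1, 1), `90` = c(1, 0),
               `135` = c(1, -1))
  nr <- nrow(modulus)
  nc <- ncol(modulus)
  out <- matrix(0, nr, nc)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      o <- offs[[as.character(bins[i, j])]]
      fwd <- modulus[i + o[1], j + o[2]]
      bwd <- modulus[i - o[1], j - o[2]]
      if (modulus[i, j] >= fwd && modulus[i, j] > bwd) {
        out[i, j] <- modulus[i, j]
      }
    }
  }
  out
}

# dense true-boundary samples of the default claw phantom, in pixel
# coordinates with the row axis measured from the top scan line
phantom_truth_xy <- function(phantom) {
  tr <- attr(phantom, "truth")
  h <- nrow(phantom)
  xs <- seq(0.5, ncol(phantom) - 0.5, by = 0.25)
  rbind(
    cbind(xs, h - evaluate_model(tr$outer, xs)$y),
    cbind(xs, h - evaluate_model(tr$inner, xs)$y)
  )
}

# analytic area between the phantom's ground-truth contours (pixel^2)
phantom_truth_area <- function(spec) {
  stats::integrate(
    function(x) {
      evaluate_model(spec$outer_curve, x)$y -
        evaluate_model(spec$inner_curve, x)$y
    },
    0, spec$width, subdivisions = 1000L
  )$value
}
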