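#' Extract ordered boundary chains from an edge map
#'
#' Labels 8-connected components of the binary edge raster and orders each
#' component into a traced chain by walking from an endpoint (or an
#' arbitrary start for closed rings) to the nearest unvisited neighbour,
#' preferring 4-neighbours over diagonals. Pixel coordinates are converted
#' to micrometres with Cartesian y measured up from the bottom scan line.
#' Chains shorter than `min_length` pixels are dropped.
#'
#' @param edges an [edge_map()] or binary matrix.
#' @param pixel_size micrometres per pixel.
#' @param min_length minimum chain length in pixels.
#' @return list of tibbles with columns `x_um`, `y_um`, ordered along the
#'   chain, each with a logical `closed` attribute; longest chain first.
#' @export
#' @examples
#' maps <- multiscale_edge_detect(generate_disk_phantom(64, 20), scales = 1)
#' chains <- extract_boundary(maps$j1)
#' length(chains)
extract_boundary <- function(edges, pixel_size = 1, min_length = 10L) {
  em <- if (inherits(edges, "edge_map")) edges$edges else edges
  storage.mode(em) <- "integer"
  if (sum(em) == 0) stop_claw("edge map is empty")
  nr <- nrow(em)

  labels <- matrix(0L, nr, ncol(em))
  comps <- list()
  idx <- which(em == 1L)
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- length(comps) + 1L
    queue <- start
    labels[start] <- lab
    members <- integer()
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, cur)
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > ncol(em)) next
        p <- (cc - 1L) * nr + rr
        if (em[p] == 1L && labels[p] == 0L) {
          labels[p] <- lab
          queue <- c(queue, p)
        }
      }
    }
    comps[[lab]] <- members
  }

  comps <- comps[lengths(comps) >= min_length]
  if (length(comps) == 0) {
    stop_claw("no chain of at least ", min_length, " pixels")
  }
  comps <- comps[order(lengths(comps), decreasing = TRUE)]

  purrr::map(comps, function(members) {
    r <- (members - 1L) %% nr + 1L
    c <- (members - 1L) %/% nr + 1L
    ord <- order_chain(r, c)
    n <- length(ord)
    closed <- n > 2 &&
      max(abs(r[ord[1]] - r[ord[n]]), abs(c[ord[1]] - c[ord[n]])) <= 1L
    out <- tibble::tibble(
      x_um = (c[ord] - 0.5) * pixel_size,
      y_um = (nr - r[ord] + 0.5) * pixel_size
    )
    attr(out, "closed") <- closed
    out
  })
}

# order component pixels into a chain: start from the pixel with fewest
# 8-neighbours (an endpoint when one exists), greedily step to the nearest
# unvisited neighbour
order_chain <- function(r, c) {
  n <- length(r)
  if (n == 1L) return(1L)
  neigh <- vapply(seq_len(n), function(i) {
    sum(abs(r - r[i]) <= 1 & abs(c - c[i]) <= 1) - 1L
  }, 0L)
  cur <- which.min(neigh)
  visited <- logical(n)
  ord <- integer(n)
  for (k in seq_len(n)) {
    ord[k] <- cur
    visited[cur] <- TRUE
    if (k == n) break
    d2 <- (r - r[cur])^2 + (c - c[cur])^2
    d2[visited] <- Inf
    cand <- which(d2 <= 2)
    cur <- if (length(cand)) cand[which.min(d2[cand])] else which.min(d2)
  }
  ord
}

#' Split a chain into x-monotone segments
#'
#' Removes consecutive points with repeated x, then splits wherever the
#' sign of `diff(x)` changes, yielding segments on which x is strictly
#' monotone — the precondition of the curve-fitting step. A closed ring
#' typically yields two segments (upper and lower arcs).
#'
#' @param points tibble with `x_um`, `y_um` ordered along the chain.
#' @param min_points segments shorter than this are dropped.
#' @return list of tibbles.
#' @export
split_monotone <- function(points, min_points = 6L) {
  xy <- boundary_xy(points)
  keep <- c(TRUE, diff(xy$x) != 0)
  x <- xy$x[keep]
  y <- xy$y[keep]
  if (length(x) < 2) return(list())
  s <- sign(diff(x))
  breaks <- which(diff(s) != 0) + 1L
  starts <- c(1L, breaks)
  ends <- c(breaks, length(x))
  segs <- purrr::map2(starts, ends, function(a, b) {
    tibble::tibble(x_um = x[a:b], y_um = y[a:b])
  })
  purrr::keep(segs, ~ nrow(.x) >= min_points)
}

#' Divide a boundary into labelled characteristic curves
#'
#' Splits the point set at the given x breakpoints into consecutive
#' segments labelled `curve1`, `curve2`, ...; a point lying exactly on a
#' breakpoint goes to the left segment. Three breakpoints give the four
#' characteristic curves used for claw-profile fitting.
#'
#' @param points tibble with `x_um`, `y_um` (x monotone).
#' @param breakpoints strictly increasing x positions inside the data
#'   range.
#' @return the input tibble with an added `segment` factor column.
#' @export
segment_curves <- function(points, breakpoints) {
  xy <- boundary_xy(points)
  if (length(breakpoints) < 1) stop_claw("need at least one breakpoint")
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop_claw("breakpoints must be strictly increasing")
  }
  rng <- range(xy$x)
  if (any(breakpoints <= rng[1]) || any(breakpoints >= rng[2])) {
    stop_claw("breakpoints must lie strictly inside the x range")
  }
  lab <- findInterval(xy$x, breakpoints, left.open = TRUE) + 1L
  tibble::tibble(
    x_um = xy$x, y_um = xy$y,
    segment = factor(paste0("curve", lab),
                     levels = paste0("curve", seq_len(length(breakpoints) + 1L)))
  )
}

#' Suggest segmentation breakpoints from curvature sign changes
#'
#' Locates the inflection points (zeros of the analytic second derivative)
#' of a boundary model on a range; segment boundaries at inflections give
#' pieces of uniform concavity, which is how the four characteristic
#' curves are delimited.
#'
#' @param model a [fourier_model()] or [fit_curve()] result.
#' @param x_range length-2 range (um).
#' @param n_grid grid resolution for bracketing sign changes.
#' @return numeric vector of x positions (possibly empty).
#' @export
suggest_breakpoints <- function(model, x_range, n_grid = 1024L) {
  x <- seq(x_range[1], x_range[2], length.out = n_grid)
  d2 <- evaluate_model(model, x)$d2y
  sgn <- sign(d2)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  vapply(flips, function(i) {
    stats::uniroot(
      function(z) evaluate_model(model, z)$d2y,
      lower = x[i], upper = x[i + 1]
    )$root
  }, 0)
}
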