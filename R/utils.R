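#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data :=
#' @useDynLib clawmech, .registration = TRUE
NULL

# argument checking helpers -------------------------------------------------

stop_claw <- function(..., class = "clawmech_error") {
  rlang::abort(paste0(...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_claw(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_claw(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) {
    stop_claw(name, " must be >= ", lower)
  }
  if (x > upper) {
    stop_claw(name, " must be <= ", upper)
  }
  invisible(x)
}

# radians/degrees -----------------------------------------------------------

#' Convert between degrees and radians
#'
#' All angle arguments in the mechanics functions are radians; sweep tables
#' report degrees. These helpers convert between the two.
#'
#' @param x numeric vector of angles.
#' @return numeric vector.
#' @export
#' @examples
#' radians(45)
#' degrees(pi / 4)
radians <- function(x) x * pi / 180

#' @rdname radians
#' @export
degrees <- function(x) x * 180 / pi

# 2-D convolution with symmetric (mirror) padding ----------------------------

mirror_index <- function(n, r) {
  # half-sample symmetric extension: ... 2 1 | 1 2 ... n | n n-1 ...
  c(rev(seq_len(min(r, n))), seq_len(n), rev(seq_len(n))[seq_len(min(r, n))])
}

mirror_pad <- function(x, r) {
  x[mirror_index(nrow(x), r), mirror_index(ncol(x), r), drop = FALSE]
}

# correlation of `x` with a small kernel `k` (odd dims), mirror-padded,
# optionally dilated by `step` (a-trous: zeros inserted between taps)
conv2_mirror <- function(x, k, step = 1L) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  r <- max(kr, kc) * step
  if (2L * r + 1L > 2L * min(dim(x))) {
    stop_claw("filter support (", 2 * r + 1, ") exceeds image extent")
  }
  xp <- mirror_pad(x, r)
  out <- matrix(0, nrow(x), ncol(x))
  ri <- r + seq_len(nrow(x))
  ci <- r + seq_len(ncol(x))
  for (a in seq_len(nrow(k))) {
    for (b in seq_len(ncol(k))) {
      w <- k[a, b]
      if (w == 0) next
      da <- (a - 1L - kr) * step
      db <- (b - 1L - kc) * step
      out <- out + w * xp[ri + da, ci + db]
    }
  }
  out
}

# separable convolution: 1-D kernel applied along rows then columns
conv2_sep_mirror <- function(x, k, step = 1L) {
  kv <- matrix(k, ncol = 1)
  conv2_mirror(conv2_mirror(x, kv, step), t(kv), step)
}

gaussian_kernel_1d <- function(sd, radius = ceiling(3 * sd)) {
  t <- seq(-radius, radius)
  k <- exp(-t^2 / (2 * sd^2))
  k / sum(k)
}

# seeded RNG scoped to a call, leaving the global stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
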