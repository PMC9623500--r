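#' @import stats
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a matrix by an integer number of pixels
#'
#' Rows move down by `dy`, columns move right by `dx`. Vacated pixels are
#' filled with `fill`. Used both by the movie generator (stage drift) and by
#' the registration routines, so that a shift followed by its inverse is
#' exactly lossless on the overlapping region.
#'
#' @param m numeric matrix.
#' @param dy,dx integer shifts in rows / columns.
#' @param fill fill value for exposed pixels.
#' @return shifted matrix of the same dimension.
#' @export
shift_matrix <- function(m, dy, dx, fill = 0) {
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

## Sub-pixel (bilinear) translation; used when applying estimated non-integer
## shifts. Out-of-range samples take `fill`.
shift_matrix_subpx <- function(m, dy, dx, fill = 0) {
  if (abs(dy - round(dy)) < 1e-9 && abs(dx - round(dx)) < 1e-9)
    return(shift_matrix(m, round(dy), round(dx), fill))
  nr <- nrow(m); nc <- ncol(m)
  r <- matrix(seq_len(nr), nr, nc) - dy
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * gv(r0, c0) +
    (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) +
    fr * fc * gv(r0 + 1, c0 + 1)
}

## Cross-correlation translation estimate via FFT. Returns the (dy, dx) that,
## applied to `moving`, best aligns it onto `fixed` (integer pixels, optional
## parabolic sub-pixel refinement).
estimate_translation <- function(fixed, moving, subpixel = TRUE) {
  stopifnot(all(dim(fixed) == dim(moving)))
  f <- fixed - mean(fixed); g <- moving - mean(moving)
  X <- fft(f) * Conj(fft(g))
  cc <- Re(fft(X, inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  idx <- which.max(cc)
  pr <- (idx - 1) %% nr + 1
  pc <- (idx - 1) %/% nr + 1
  dy <- pr - 1; dx <- pc - 1
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  if (subpixel) {
    gp <- function(i, j) cc[(i - 1) %% nr + 1, (j - 1) %% nc + 1]
    par1 <- function(m1, m0, p1) {
      den <- m1 - 2 * m0 + p1
      if (abs(den) < 1e-12) 0 else 0.5 * (m1 - p1) / den
    }
    dy <- dy + par1(gp(pr - 1, pc), gp(pr, pc), gp(pr + 1, pc))
    dx <- dx + par1(gp(pr, pc - 1), gp(pr, pc), gp(pr, pc + 1))
  }
  c(dy = dy, dx = dx)
}

## 8-connected labelling built on EBImage::bwlabel (which is 4-connected):
## labels are merged wherever two components touch diagonally.
label_components8 <- function(binary) {
  m <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dd in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1), , drop = FALSE]
    b <- lab[-1, , drop = FALSE]
    if (dd[2] == 1L) { a <- a[, seq_len(nc - 1), drop = FALSE]; b <- b[, -1, drop = FALSE] }
    else             { a <- a[, -1, drop = FALSE];              b <- b[, seq_len(nc - 1), drop = FALSE] }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

## Distance and angle grids about a (row, col) centre, in pixel units.
## Pixel centres sit at integer coordinates (row, col), origin top-left.
radial_grids <- function(nrow_px, ncol_px, center) {
  dy <- seq_len(nrow_px) - center[1]
  dx <- seq_len(ncol_px) - center[2]
  r <- sqrt(outer(dy^2, dx^2, `+`))
  theta <- atan2(matrix(dy, nrow_px, ncol_px), matrix(dx, nrow_px, ncol_px, byrow = TRUE))
  list(r = r, theta = theta)
}

## Does angle x (rad, any range) fall within [a1, a2] measured
## counter-clockwise from a1? Handles wrap-around.
angle_in_interval <- function(x, a1, a2) {
  tw <- (a2 - a1) %% (2 * pi)
  if (tw == 0) tw <- 2 * pi
  ((x - a1) %% (2 * pi)) <= tw
}

## Run a block with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
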