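# Shared fixtures. Heavy objects (generated movies, classifiers) are built
# lazily once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Desk-scale preset for unit tests: same physics, 168 px / 0.039 mm/px /
# 1 h frames, so a movie generates in well under a second.
tiny_preset <- function(strain = "wt_2740_80", ...) {
  args <- utils::modifyList(
    list(image_size_px = 168L, pixel_size_mm = 0.039, dt_h = 1,
         drift = list(step_sd_px = 0.3, max_px = 3)),
    list(...))
  do.call(make_preset, c(list(strain), args))
}

tiny_noise_free <- function(strain = "wt_2740_80", ...) {
  tiny_preset(strain,
              noise = list(poisson_gain = 0, read_sd = 0, background = 20),
              drift = list(step_sd_px = 0, max_px = 3), ...)
}

tiny_movie <- function() fixture("tiny_movie", generate_movie(tiny_preset(), seed = 1))

tiny_movie_nf <- function() fixture("tiny_movie_nf", generate_movie(tiny_noise_free(), seed = 1))

# a centred binary disk image
disk_image <- function(n, radius, center = c((n + 1) / 2, (n + 1) / 2),
                       value = 1, background = 0) {
  g <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, `+`)
  ifelse(sqrt(g) <= radius, value, background)
}

# brute-force per-pixel circumferential average (oracle)
oracle_circumferential <- function(frame, center, theta_min, theta_max,
                                   bin_width = 1, n_bins) {
  sums <- numeric(n_bins); cnts <- numeric(n_bins)
  full <- isTRUE(all.equal((theta_max - theta_min) %% (2 * pi), 0))
  for (i in seq_len(nrow(frame))) for (j in seq_len(ncol(frame))) {
    dy <- i - center[1]; dx <- j - center[2]
    r <- sqrt(dy^2 + dx^2)
    b <- floor(r / bin_width) + 1
    if (b > n_bins) next
    th <- atan2(dy, dx)
    ok <- full || ((th - theta_min) %% (2 * pi)) <= ((theta_max - theta_min) %% (2 * pi))
    if (ok) { sums[b] <- sums[b] + frame[i, j]; cnts[b] <- cnts[b] + 1 }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

# brute-force flood fill component areas, 8-connectivity (oracle)
oracle_component_areas <- function(binary) {
  visited <- matrix(FALSE, nrow(binary), ncol(binary))
  areas <- integer()
  for (i0 in seq_len(nrow(binary))) for (j0 in seq_len(ncol(binary))) {
    if (!binary[i0, j0] || visited[i0, j0]) next
    stack_px <- list(c(i0, j0)); visited[i0, j0] <- TRUE; a <- 0L
    while (length(stack_px)) {
      p <- stack_px[[length(stack_px)]]; stack_px[[length(stack_px)]] <- NULL
      a <- a + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii < 1 || jj < 1 || ii > nrow(binary) || jj > ncol(binary)) next
        if (binary[ii, jj] && !visited[ii, jj]) {
          visited[ii, jj] <- TRUE
          stack_px[[length(stack_px) + 1]] <- c(ii, jj)
        }
      }
    }
    areas <- c(areas, a)
  }
  sort(areas)
}

# brute-force grayscale opening with a disc (oracle for rolling ball)
oracle_opening <- function(image, radius) {
  d <- 2 * radius + 1
  off <- which(outer((-radius:radius)^2, (-radius:radius)^2, `+`) <= radius^2,
               arr.ind = TRUE) - radius - 1
  nr <- nrow(image); nc <- ncol(image)
  ero <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    ero[i, j] <- min(image[cbind(ii[ok], jj[ok])])
  }
  dil <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    dil[i, j] <- max(ero[cbind(ii[ok], jj[ok])])
  }
  dil
}

# exhaustive-search Renyi entropy threshold for one order (oracle)
oracle_renyi_order <- function(p, alpha) {
  best <- -Inf; best_t <- 0L
  P1 <- cumsum(p)
  for (t in 0:(length(p) - 2)) {
    w1 <- P1[t + 1]; w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    pb <- p[1:(t + 1)] / w1; pf <- p[(t + 2):length(p)] / w2
    ent <- if (alpha == 1) {
      -sum(pb[pb > 0] * log(pb[pb > 0])) - sum(pf[pf > 0] * log(pf[pf > 0]))
    } else (log(sum(pb^alpha)) + log(sum(pf^alpha))) / (1 - alpha)
    if (ent > best) { best <- ent; best_t <- t }
  }
  best_t
}
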