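# Shared fixtures and independent oracles, all built in code at test time.

# small deterministic volume with two intensity plateaus
tiny_volume <- function(d = c(4, 5, 6), lo = 100, hi = 160, seed = NULL) {
  arr <- array(lo, d)
  arr[, , (d[3] %/% 2 + 1):d[3]] <- hi
  if (!is.null(seed)) {
    set.seed(seed)
    arr <- arr + array(rnorm(prod(d)), d)
  }
  ct_volume(arr)
}

# naive per-window histogram, the oracle for the integral-histogram path
naive_profiles <- function(feature, window, breaks) {
  nb <- length(breaks) - 1
  nr <- nrow(feature); nc <- ncol(feature)
  h <- (window - 1) %/% 2
  bin <- matrix(findInterval(feature, breaks, all.inside = TRUE), nr, nc)
  prob <- array(0, c(nr, nc, nb))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rows <- max(1, r - h):min(nr, r + h)
    cols <- max(1, c - h):min(nc, c + h)
    tab <- tabulate(bin[rows, cols], nbins = nb)
    prob[r, c, ] <- tab / sum(tab)
  }
  prob
}

# exhaustive all-simple-paths likelihood oracle (unit spacing, delta_dis 1)
exhaustive_likelihood <- function(vol, seed_idx, mu, eps = 1e-6) {
  d <- dim(vol$intensities); n <- prod(d)
  I <- as.vector(vol$intensities)
  nbrs <- function(v) {
    a <- arrayInd(v, d); out <- integer(0)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      b <- a; b[ax] <- b[ax] + s
      if (b[ax] >= 1 && b[ax] <= d[ax])
        out <- c(out, (b[3] - 1) * d[1] * d[2] + (b[2] - 1) * d[1] + b[1])
    }
    out
  }
  best <- rep(0, n); best[seed_idx] <- 1
  for (s in seed_idx) {
    vis0 <- rep(FALSE, n); vis0[s] <- TRUE
    stack <- list(list(v = s, ibar = I[s], dis = 1, st = 1, vis = vis0))
    while (length(stack)) {
      nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (w in nbrs(nd$v)) {
        if (nd$vis[w] || w %in% seed_idx) next
        step <- exp(-mu * (I[w] - nd$ibar)^2 / (1 + nd$dis))
        st <- min(nd$st, step)
        if (st > best[w]) best[w] <- st
        vis <- nd$vis; vis[w] <- TRUE
        stack[[length(stack) + 1]] <-
          list(v = w, ibar = (I[w] + nd$ibar) / 2, dis = nd$dis + 1,
               st = st, vis = vis)
      }
    }
  }
  array(pmin(pmax(best, eps), 1), d)
}

# exhaustive minimum over all 2^n labelings of a pairwise energy
exhaustive_min_energy <- function(edges, ncap, scap, tcap) {
  n <- length(scap)
  labs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  data_e <- labs %*% tcap + (!labs) %*% scap
  cut_e <- if (nrow(edges)) {
    diff <- labs[, edges[, 1], drop = FALSE] != labs[, edges[, 2],
                                                    drop = FALSE]
    diff %*% ncap
  } else 0
  min(data_e + cut_e)
}

# random small 3D grid graph with random data and boundary weights
random_grid_graph <- function() {
  dims <- list(c(2, 2, 1), c(3, 2, 1), c(2, 2, 2), c(3, 2, 2), c(2, 3, 2),
               c(4, 3, 1), c(12, 1, 1), c(3, 4, 1), c(3, 3, 1))
  d <- dims[[sample(length(dims), 1)]]
  n <- prod(d)
  idx <- array(seq_len(n), d)
  ea <- integer(0); eb <- integer(0)
  if (d[1] > 1) { ea <- c(ea, idx[-d[1], , ]); eb <- c(eb, idx[-1, , ]) }
  if (d[2] > 1) { ea <- c(ea, idx[, -d[2], ]); eb <- c(eb, idx[, -1, ]) }
  if (d[3] > 1) { ea <- c(ea, idx[, , -d[3]]); eb <- c(eb, idx[, , -1]) }
  list(edges = cbind(ea, eb), ncap = runif(length(ea), 0, 1.5),
       scap = runif(n, 0, 3), tcap = runif(n, 0, 3), dim = d)
}

# random non-empty blob mask
random_blob <- function(d = c(10, 10, 10)) {
  center <- sapply(d, function(k) runif(1, 3, k - 2))
  radius <- runif(1, 1.5, 3.5)
  s <- slice.index(array(0, d), 1)
  r <- slice.index(array(0, d), 2)
  c <- slice.index(array(0, d), 3)
  m <- (s - center[1])^2 + (r - center[2])^2 + (c - center[3])^2 <= radius^2
  extra <- sample(prod(d), 3)
  m[extra] <- TRUE
  m
}

# 4-neighbour border + 1-px chebyshev band around the truth contour of a slice
contour_band <- function(truth2d) {
  nr <- nrow(truth2d); nc <- ncol(truth2d)
  shf <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  inner <- truth2d & shf(truth2d, 1, 0) & shf(truth2d, -1, 0) &
    shf(truth2d, 0, 1) & shf(truth2d, 0, -1)
  border <- truth2d & !inner
  band <- border
  for (dr in -1:1) for (dc in -1:1) band <- band | shf(border, dr, dc)
  list(border = border, band = band, interior = truth2d & !band)
}

# enhanced mid-slice of a slab phantom, shared by the ACO property tests
slab_enhanced_slice <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(phantom_spec(dim = c(16, 64, 64)))
      enh <- enhanced_image(ph$volume, ph$seeds)
      cache <<- list(slice = enh$enhanced[8, , ],
                     truth2d = ph$truth$labels[8, , ])
    }
    cache
  }
})
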