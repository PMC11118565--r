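# Independent brute-force oracles used to cross-check the implementation.

# queue-based flood fill labeling (pure R, no shared code with the package)
flood_fill_label <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] == 0 || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[1, 2] + nb[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] != 0 && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# label partitions are equal up to renaming
same_partition <- function(a, b) {
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  length(unique(paste(a[fg], b[fg]))) == max(a) &&
    max(a) == max(b)
}

# exhaustive-search Otsu over the same 256-bin histogram convention
otsu_exhaustive <- function(frame, nbins = 256L) {
  v <- as.numeric(frame)
  rng <- range(v)
  w <- (rng[2] - rng[1]) / nbins
  idx <- pmin(floor((v - rng[1]) / w) + 1L, nbins)
  h <- tabulate(idx, nbins)
  ctr <- rng[1] + (seq_len(nbins) - 0.5) * w
  best <- -Inf; best_t <- NA
  for (t in seq_len(nbins - 1L)) {
    n0 <- sum(h[1:t]); n1 <- sum(h) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[1:t] * ctr[1:t]) / n0
    mu1 <- sum(h[(t + 1):nbins] * ctr[(t + 1):nbins]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  ctr[best_t]
}

# direct convolution Sobel oracle, replicate padding, explicit loops
sobel_brute <- function(frame) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  nr <- nrow(frame); nc <- ncol(frame)
  at <- function(i, j) frame[min(max(i, 1), nr), min(max(j, 1), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx <- 0; gy <- 0
    for (a in -1:1) for (b in -1:1) {
      gx <- gx + kx[a + 2, b + 2] * at(i + a, j + b)
      gy <- gy + ky[a + 2, b + 2] * at(i + a, j + b)
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# two-sided Fisher exact p by explicit hypergeometric enumeration with choose()
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  p_obs <- prob(a)
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <=
                                     p_obs * (1 + 1e-7)])
}

# overlap-graph reachability oracle via igraph on an independently built graph
link_oracle_components <- function(frames, footprints, gap_window) {
  n <- length(frames)
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    df <- abs(frames[j] - frames[i])
    if (df >= 1 && df <= gap_window + 1 &&
        length(intersect(footprints[[i]], footprints[[j]])))
      edges <- rbind(edges, c(i, j))
  }
  if (is.null(edges)) return(rep(NA_integer_, n))
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  memb[igraph::degree(g) == 0] <- NA_integer_   # non-persistent
  memb
}

# small noiseless default scene for pipeline tests
test_scene <- function(field = c(192, 192), n_frames = 10, noise = FALSE,
                       psf = 0, seed = 1, ...) {
  sim_scene(field = field, n_frames = n_frames, psf_sigma = psf,
            noise = noise, camera_offset = 0, seed = seed, ...)
}
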