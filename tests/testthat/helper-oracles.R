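# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: plain-R exhaustive scans, BFS/Dijkstra on small
# grids, and brute-force assignment enumeration.

pop_var <- function(v) mean((v - mean(v))^2)

# Exhaustive Otsu scan directly on pixel values: for every split
# "<= v vs > v" over the distinct values, compute the weighted intra-class
# variance; return the smallest minimizing split value.
oracle_otsu_split <- function(x) {
  x <- as.numeric(x)
  vals <- sort(unique(x))
  n <- length(x)
  best_v <- NA_real_; best_s <- Inf
  for (v in vals[-length(vals)]) {
    lo <- x[x <= v]; hi <- x[x > v]
    s <- length(lo) / n * pop_var(lo) + length(hi) / n * pop_var(hi)
    if (s < best_s - 1e-12) { best_s <- s; best_v <- v }
  }
  list(split = best_v, sigma_w2 = best_s)
}

# 8-connected components by plain-R BFS.
oracle_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Nearest-marker-by-geodesic-distance partition of a mask (multi-source
# Dijkstra on the 8-connected grid, orthogonal steps 1, diagonal sqrt(2)).
oracle_geodesic_partition <- function(mask, markers) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc); lab <- matrix(0L, nr, nc)
  idx <- which(markers > 0L)
  frontier <- data.frame(i = idx, d = 0)
  dist[idx] <- 0; lab[idx] <- markers[idx]
  while (nrow(frontier)) {
    k <- which.min(frontier$d)
    cur <- frontier$i[k]; cd <- frontier$d[k]
    frontier <- frontier[-k, ]
    if (cd > dist[cur]) next
    ci <- (cur - 1L) %% nr + 1L; cj <- (cur - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- ci + dr; c <- cj + dc
      if (r < 1 || r > nr || c < 1 || c > nc || !mask[r, c]) next
      nd <- cd + sqrt(dr^2 + dc^2)
      tgt <- r + (c - 1L) * nr
      if (nd < dist[tgt] - 1e-9) {
        dist[tgt] <- nd; lab[tgt] <- lab[cur]
        frontier <- rbind(frontier, data.frame(i = tgt, d = nd))
      }
    }
  }
  lab
}

# Brute-force maximum one-to-one matching among pairs with iou >= t.
oracle_max_matching <- function(pairs, t) {
  cand <- pairs[pairs$iou >= t, , drop = FALSE]
  if (nrow(cand) == 0L) return(0L)
  gts <- unique(cand$gt_id)
  rec <- function(i, used_pred) {
    if (i > length(gts)) return(0L)
    best <- rec(i + 1L, used_pred)
    rows <- cand[cand$gt_id == gts[i] & !(cand$pred_id %in% used_pred), ,
                 drop = FALSE]
    for (p in rows$pred_id) best <- max(best, 1L + rec(i + 1L, c(used_pred, p)))
    best
  }
  rec(1L, integer(0))
}

disc_mask <- function(nr, nc, cy, cx, r) {
  outer(seq_len(nr) - cy, seq_len(nc) - cx,
        function(dy, dx) dy^2 + dx^2 <= r^2)
}

# Random small label maps (<= max_n instances) for matching tests: discs
# dropped on a grid, later discs yield contested pixels to earlier ones.
random_label_map <- function(nr = 32, nc = 32, max_n = 6) {
  n <- sample.int(max_n, 1)
  lab <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    m <- disc_mask(nr, nc, runif(1, 5, nr - 5), runif(1, 5, nc - 5),
                   runif(1, 2.5, 5))
    lab[m & lab == 0L] <- k
  }
  lab
}

small_spec <- function(seed, ...) {
  args <- list(image_height = 192L, image_width = 192L, n_single = 6L,
               n_touching_pairs = 2L, n_clusters = 1L, cluster_size = 3L,
               n_debris = 3L, seed = seed)
  do.call(synthetic_spec, utils::modifyList(args, list(...)))
}
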