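# Independent brute-force oracles and small generators used across tests.
# These deliberately re-derive results from first principles (plain loops),
# not by calling the package's implementation paths.

# random tree plot with uniform positions and heights
random_plot <- function(n, bounds = c(0, 0, 100, 100), hmin = 2, hmax = 25,
                        seed = 1, dbh = FALSE, crown = FALSE) {
  set.seed(seed)
  tr <- data.frame(tree_id = sprintf("t%03d", seq_len(n)),
                   x_m = runif(n, bounds[1], bounds[3]),
                   y_m = runif(n, bounds[2], bounds[4]),
                   height_m = runif(n, hmin, hmax))
  if (dbh) tr$dbh_cm <- 4.29 * tr$height_m^0.68
  if (crown) tr$crown_radius_m <- pmax(0.3, 0.5 + 0.14 * tr$height_m)
  tree_plot(tr, bounds = bounds)
}

# brute-force variable-window local-maximum predicate at every cell,
# then single-representative plateau rule (smallest row, then col, among
# connected equal passing cells)
oracle_treetops <- function(ch, min_height_m = 1.37) {
  v <- ch$values
  v[!is.finite(v)] <- 0
  ny <- nrow(v); nx <- ncol(v); cs <- ch$cell_size_m
  pass <- matrix(FALSE, ny, nx)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    h <- v[r, c]
    if (h < min_height_m) next
    rad <- 0.2 * h
    kr <- floor(rad / cs + 1e-9)
    ok <- TRUE
    for (r2 in max(1, r - kr):min(ny, r + kr)) {
      rem <- rad^2 + 1e-12 - ((r2 - r) * cs)^2
      if (rem < 0) next
      kc <- floor(sqrt(rem) / cs)
      cols <- max(1, c - kc):min(nx, c + kc)
      if (any(v[r2, cols] > h)) {
        ok <- FALSE
        break
      }
    }
    pass[r, c] <- ok
  }
  cells <- which(pass, arr.ind = TRUE)
  if (nrow(cells) == 0) {
    return(data.frame(row = integer(0), col = integer(0)))
  }
  # BFS plateau grouping over passing equal-valued 8-neighbors
  visited <- matrix(FALSE, ny, nx)
  reps <- list()
  ord <- order(cells[, 1], cells[, 2])
  for (k in ord) {
    r0 <- cells[k, 1]; c0 <- cells[k, 2]
    if (visited[r0, c0]) next
    queue <- list(c(r0, c0))
    visited[r0, c0] <- TRUE
    best <- c(r0, c0)
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (cur[1] < best[1] || (cur[1] == best[1] && cur[2] < best[2])) {
        best <- cur
      }
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 >= 1 && r2 <= ny && c2 >= 1 && c2 <= nx &&
            !visited[r2, c2] && pass[r2, c2] &&
            v[r2, c2] == v[cur[1], cur[2]]) {
          visited[r2, c2] <- TRUE
          queue <- c(queue, list(c(r2, c2)))
        }
      }
    }
    reps[[length(reps) + 1]] <- best
  }
  out <- do.call(rbind, reps)
  data.frame(row = out[, 1], col = out[, 2])
}

# treetop tibble -> sorted (row, col) grid indices for set comparison
treetops_to_cells <- function(tops, ch) {
  cs <- ch$cell_size_m
  data.frame(row = round((tops$y_m - ch$origin[2]) / cs + 0.5),
             col = round((tops$x_m - ch$origin[1]) / cs + 0.5))
}

cells_key <- function(df) sort(paste(df$row, df$col))

# step-by-step replay of the stated greedy matching rule
oracle_greedy_match <- function(uas, field, max_dist = 4, max_he = 2) {
  u <- as.data.frame(uas)[order(-uas$height_m, uas$tree_id), ]
  f <- as.data.frame(field)
  f$used <- FALSE
  pairs <- list()
  for (i in seq_len(nrow(u))) {
    best <- NULL
    for (j in seq_len(nrow(f))) {
      if (f$used[j]) next
      d <- sqrt((f$x_m[j] - u$x_m[i])^2 + (f$y_m[j] - u$y_m[i])^2)
      he <- abs(f$height_m[j] - u$height_m[i])
      if (d > max_dist || he >= max_he) next
      cand <- list(j = j, he = he, d = d, id = f$tree_id[j])
      if (is.null(best) || cand$he < best$he ||
          (cand$he == best$he && cand$d < best$d) ||
          (cand$he == best$he && cand$d == best$d && cand$id < best$id)) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      f$used[best$j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(u$tree_id[i], best$id)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(uas_id = character(0), field_id = character(0)))
  }
  m <- do.call(rbind, pairs)
  data.frame(uas_id = m[, 1], field_id = m[, 2])
}

# plain union-find connected components at distance <= eps;
# returns a canonical partition signature
oracle_components <- function(x, y, eps) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && (x[i] - x[j])^2 + (y[i] - y[j])^2 <= eps^2) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

partition_signature <- function(groups) {
  unname(sort(vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}
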