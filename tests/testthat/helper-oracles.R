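# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and must stay independent of the package's implementation paths.

# 26-connected labelling by breadth-first flood fill in plain R.
flood_fill_labels <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      p <- arrayInd(cur, dims)
      for (r in seq_len(nrow(nb))) {
        q <- p + nb[r, ]
        if (any(q < 1) || any(q > dims)) next
        j <- q[1] + dims[1] * (q[2] - 1) + dims[1] * dims[2] * (q[3] - 1)
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Component voxel counts from the flood-fill oracle, sorted decreasing.
flood_fill_sizes <- function(mask) {
  lab <- flood_fill_labels(mask)
  if (max(lab) == 0L) return(integer(0))
  sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
}

# One-way ANOVA by explicit sums of squares.
brute_anova1 <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  lv <- unique(groups)
  ss_between <- sum(vapply(lv, function(g) {
    v <- values[groups == g]
    length(v) * (mean(v) - gm)^2
  }, numeric(1)))
  ss_within <- sum(vapply(lv, function(g) {
    v <- values[groups == g]
    sum((v - mean(v))^2)
  }, numeric(1)))
  df_b <- length(lv) - 1
  df_w <- length(values) - length(lv)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(ss_total = ss_total, ss_between = ss_between, ss_within = ss_within,
       df_between = df_b, df_within = df_w, f = f,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# Balanced two-way ANOVA with interaction by explicit sums of squares.
brute_anova2 <- function(values, fa, fb) {
  fa <- as.character(fa); fb <- as.character(fb)
  gm <- mean(values)
  la <- unique(fa); lb <- unique(fb)
  n_cell <- length(values) / (length(la) * length(lb))
  ma <- vapply(la, function(a) mean(values[fa == a]), numeric(1))
  mb <- vapply(lb, function(b) mean(values[fb == b]), numeric(1))
  ss_a <- n_cell * length(lb) * sum((ma - gm)^2)
  ss_b <- n_cell * length(la) * sum((mb - gm)^2)
  ss_ab <- 0
  ss_err <- 0
  for (a in la) for (b in lb) {
    v <- values[fa == a & fb == b]
    mc <- mean(v)
    ss_ab <- ss_ab + n_cell * (mc - ma[a] - mb[b] + gm)^2
    ss_err <- ss_err + sum((v - mc)^2)
  }
  df_a <- length(la) - 1
  df_b <- length(lb) - 1
  df_ab <- df_a * df_b
  df_err <- length(values) - length(la) * length(lb)
  list(ss_a = unname(ss_a), ss_b = unname(ss_b), ss_ab = unname(ss_ab),
       ss_err = unname(ss_err), ss_total = sum((values - gm)^2),
       f_a = unname((ss_a / df_a) / (ss_err / df_err)),
       f_b = unname((ss_b / df_b) / (ss_err / df_err)),
       f_ab = unname((ss_ab / df_ab) / (ss_err / df_err)),
       df = c(df_a, df_b, df_ab, df_err))
}

# Greedy matching of detected events to ground-truth events by transition,
# type and physical distance; returns tp/fp/fn.
match_events <- function(true_ev, det_ev, tol_um = 1.5,
                         voxel_z_um = 0.25, voxel_xy_um = 0.1) {
  tp <- 0L
  used <- rep(FALSE, nrow(det_ev))
  for (i in seq_len(nrow(true_ev))) {
    cand <- which(!used & det_ev$frame_from == true_ev$frame_from[i] &
                    det_ev$type == true_ev$type[i])
    if (!length(cand)) next
    d <- sqrt(((det_ev$z[cand] - true_ev$z[i]) * voxel_z_um)^2 +
                ((det_ev$y[cand] - true_ev$y[i]) * voxel_xy_um)^2 +
                ((det_ev$x[cand] - true_ev$x[i]) * voxel_xy_um)^2)
    j <- cand[which.min(d)]
    if (min(d) <= tol_um) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  c(tp = tp, fp = nrow(det_ev) - tp, fn = nrow(true_ev) - tp)
}

# A random scene of non-touching solid boxes/spheres for labelling oracles.
random_blob_mask <- function(dims, n_blobs, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mask <- array(FALSE, dims)
  placed <- 0
  for (try in 1:(n_blobs * 30)) {
    if (placed >= n_blobs) break
    r <- sample(1:2, 1)
    c0 <- c(sample((r + 1):(dims[1] - r), 1), sample((r + 1):(dims[2] - r), 1),
            sample((r + 1):(dims[3] - r), 1))
    zz <- (c0[1] - r):(c0[1] + r)
    yy <- (c0[2] - r):(c0[2] + r)
    xx <- (c0[3] - r):(c0[3] + r)
    # keep one empty voxel of clearance so blobs stay distinct components
    zc <- max(1, min(zz) - 1):min(dims[1], max(zz) + 1)
    yc <- max(1, min(yy) - 1):min(dims[2], max(yy) + 1)
    xc <- max(1, min(xx) - 1):min(dims[3], max(xx) + 1)
    if (any(mask[zc, yc, xc])) next
    mask[zz, yy, xx] <- TRUE
    placed <- placed + 1
  }
  mask
}

# Evaluate expr under a fixed seed without disturbing the session RNG.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
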