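# Independent brute-force oracles, deliberately written with explicit loops
# and closed forms, never calling the implementation paths they check.

# closed-form OLS slope/intercept
ols_slope <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  s <- 0; d <- 0
  for (i in seq_along(x)) {
    s <- s + (x[i] - xb) * (y[i] - yb)
    d <- d + (x[i] - xb)^2
  }
  c(slope = s / d, intercept = yb - (s / d) * xb)
}

# naive binned ROI relaxivity: explicit loop over bins
naive_roi_relaxivity <- function(r1, r2star, n_bins = 36,
                                 rate_range = c(0, 50),
                                 min_bin_frac = 0.04) {
  total <- length(r2star)
  width <- (rate_range[2] - rate_range[1]) / n_bins
  med_x <- c(); med_y <- c(); counts <- integer(n_bins)
  retained <- logical(n_bins)
  all_mx <- rep(NA_real_, n_bins); all_my <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    lo <- rate_range[1] + (b - 1) * width
    hi <- rate_range[1] + b * width
    sel <- r2star >= lo & r2star < hi
    counts[b] <- sum(sel)
    if (counts[b] > 0) {
      all_mx[b] <- stats::median(r2star[sel])
      all_my[b] <- stats::median(r1[sel])
    }
    if (counts[b] > 0 && !(counts[b] < min_bin_frac * total)) {
      retained[b] <- TRUE
      med_x <- c(med_x, all_mx[b])
      med_y <- c(med_y, all_my[b])
    }
  }
  fit <- ols_slope(med_x, med_y)
  list(slope = unname(fit["slope"]), intercept = unname(fit["intercept"]),
       counts = counts, retained = retained,
       median_r2star = all_mx, median_r1 = all_my)
}

# naive BH step-up, same op order as the classic formula (n/i) * p_(i)
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    v <- n / i * p[o[i]]
    if (v < running) running <- v
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# permutation oracle for slope-homogeneity F across two groups: permutes y
# (with x fixed) within the pooled sample across groups
perm_ancova_p <- function(x1, y1, x2, y2, n_perm = 20000, seed = 1) {
  fstat <- function(xa, ya, xb, yb) {
    rss_sep <- function(x, y) {
      f <- ols_slope(x, y)
      sum((y - f["intercept"] - f["slope"] * x)^2)
    }
    rss1 <- rss_sep(xa, ya) + rss_sep(xb, yb)
    # common slope, separate intercepts
    xa_c <- xa - mean(xa); xb_c <- xb - mean(xb)
    ya_c <- ya - mean(ya); yb_c <- yb - mean(yb)
    bc <- (sum(xa_c * ya_c) + sum(xb_c * yb_c)) / (sum(xa_c^2) + sum(xb_c^2))
    rss0 <- sum((ya_c - bc * xa_c)^2) + sum((yb_c - bc * xb_c)^2)
    df2 <- length(xa) + length(xb) - 4
    (rss0 - rss1) / 1 / (rss1 / df2)
  }
  obs <- fstat(x1, y1, x2, y2)
  set.seed(seed)
  n1 <- length(x1)
  y <- c(y1, y2)
  count <- 0
  for (k in seq_len(n_perm)) {
    yp <- sample(y)
    if (fstat(x1, yp[1:n1], x2, yp[-(1:n1)]) >= obs) count <- count + 1
  }
  (count + 1) / (n_perm + 1)
}

# exhaustive two-sample KS p-value by enumeration over label assignments
enum_ks_p <- function(a, b) {
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(vapply(v, function(t) abs(mean(a <= t) - mean(b <= t)), 0))
  }
  obs <- ks_stat(a, b)
  pool <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pool), n)
  cnt <- 0
  for (j in seq_len(ncol(idx))) {
    aa <- pool[idx[, j]]
    bb <- pool[-idx[, j]]
    if (ks_stat(aa, bb) >= obs - 1e-12) cnt <- cnt + 1
  }
  cnt / ncol(idx)
}

# brute-force sliding-window slope at a single voxel
naive_window_slope <- function(r1, r2star, mask, at, box = 5,
                               min_in_mask = 10) {
  r <- (box - 1) / 2
  d <- dim(r1)
  xs <- c(); ys <- c()
  used <- 0
  for (i in max(1, at[1] - r):min(d[1], at[1] + r))
    for (j in max(1, at[2] - r):min(d[2], at[2] + r))
      for (k in max(1, at[3] - r):min(d[3], at[3] + r))
        if (mask[i, j, k]) {
          used <- used + 1
          xs <- c(xs, r2star[i, j, k])
          ys <- c(ys, r1[i, j, k])
        }
  if (!mask[at[1], at[2], at[3]] || used < min_in_mask)
    return(list(slope = NaN, n = used))
  list(slope = unname(ols_slope(xs, ys)["slope"]), n = used)
}

# small brain phantom spec reused across tests
demo_rois <- function() {
  data.frame(label = c(1L, 2L, 3L, 4L),
             slope = c(0.005, 0.012, 0.020, 0.035),
             intercept = c(0.25, 0.30, 0.35, 0.20),
             r2star_min = c(10, 12, 15, 18),
             r2star_max = c(22, 26, 32, 40))
}
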