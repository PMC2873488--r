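# Shared fixtures, built once per test run.

# Memoized synthetic panels: the small 3-target panel for unit tests and
# the 6-target panel used by the sensitivity/negative-control checks.
.panel_cache <- new.env(parent = emptyenv())

small_panel <- function() {
  if (is.null(.panel_cache$small)) {
    .panel_cache$small <- synth_panel(n_targets = 3L, length_nt = 200L,
                                      seed = 7L, n_subarrays = 2L)
  }
  .panel_cache$small
}

# 8-probe panel whose first 6 targets form the artificial mix; the two
# remaining probes stay silent and witness specificity.
mix_panel <- function() {
  if (is.null(.panel_cache$mix)) {
    .panel_cache$mix <- synth_panel(n_targets = 8L, length_nt = 300L,
                                    seed = 7L, n_subarrays = 8L)
  }
  .panel_cache$mix
}

# Independent Welch one-sided p-value (hand-rolled formula, not t.test).
welch_one_sided_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  1 - pt(t, df)
}

# Brute-force Ward agglomeration via the Lance-Williams update used by
# the ward.D2 criterion, tracking merge order and heights.
brute_force_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  active <- as.list(seq_len(n))      # leaf sets
  ids <- -seq_len(n)                 # hclust-style negative leaf codes
  sizes <- rep(1L, n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(Inf, 0L, 0L)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights[step] <- d[i, j]
    merges[step, ] <- c(ids[[i]], ids[[j]])
    ni <- sizes[i]; nj <- sizes[j]
    newd <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      newd[k] <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                         nk * d[i, j]^2) / (ni + nj + nk))
    }
    d[i, ] <- newd; d[, i] <- newd; d[i, i] <- 0
    keep <- setdiff(seq_len(m), j)
    d <- d[keep, keep, drop = FALSE]
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    ids[i] <- step
    active <- active[keep]; sizes <- sizes[keep]; ids <- ids[keep]
  }
  list(merges = merges, heights = heights)
}

# Canonical set-of-splits representation for topology comparison.
tree_splits <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", n - 1L)
  get_leaves <- function(id) {
    if (id < 0) hc$labels[-id] else members[[id]]
  }
  for (k in seq_len(n - 1L)) {
    members[[k]] <- sort(c(get_leaves(hc$merge[k, 1]),
                           get_leaves(hc$merge[k, 2])))
  }
  sort(vapply(members, paste, character(1), collapse = "|"))
}
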