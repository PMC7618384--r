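# Independent oracles used across the suite. Deliberately written without
# touching package internals: plain enumeration, brute-force joins, direct
# formulas on raw values.

# two-sided Mann-Whitney p by full enumeration of group assignments
enum_mwu_p <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  N <- length(r)
  mu <- n1 * (N - n1) / 2
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(N, n1)
  us <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Kruskal-Wallis H by the direct rank-sum formula with tie correction
kw_H_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) 0 else H / C
}

# Dunn z for one pair by the mean-rank / pooled-variance formula
dunn_z_oracle <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  tie <- table(x)
  TS <- sum(tie^3 - tie)
  V <- (N * (N + 1) / 12 - TS / (12 * (N - 1))) *
    (1 / lengths(groups)[i] + 1 / lengths(groups)[j])
  (rbar[[i]] - rbar[[j]]) / sqrt(V)
}

# cardinality of the discrete Euclidean disk by exhaustive enumeration
disk_count_oracle <- function(r) {
  n <- 0L
  for (dy in -r:r) for (dx in -r:r) if (dy^2 + dx^2 <= r^2) n <- n + 1L
  n
}

# IsoData fixed point computed directly on the raw values
isodata_oracle <- function(x, tol = 1e-10) {
  t <- mean(x)
  repeat {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) return(t)
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
}

# ligand-receptor matching by brute-force nested loops
brute_lr_join <- function(ligands, db, receiver, thr) {
  hits <- integer()
  for (i in seq_len(nrow(db))) {
    if (!db$ligand[i] %in% ligands) next
    ok <- TRUE
    for (g in db$receptors[[i]]) {
      e <- if (g %in% names(receiver)) receiver[[g]] else 0
      if (!(e > thr)) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# two-sided Fisher p for the (matched, unmatched) x (pre, post) table by
# exhaustive hypergeometric tail enumeration
fisher_two_sided_oracle <- function(pre, post, universe) {
  m <- pre + post             # total matched
  obs <- stats::dhyper(pre, m, 2 * universe - m, universe)
  ks <- max(0, m - universe):min(m, universe)
  probs <- stats::dhyper(ks, m, 2 * universe - m, universe)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# first seed whose scene satisfies the exactness precondition of
# pairwise non-touching nuclei (a fixture filter, not an outcome filter)
find_separated_scene <- function(acq, mural_density = 6, fibroblast_density = 4,
                                 from = 1L, tries = 100L) {
  for (s in from + seq_len(tries) - 1L) {
    sp <- default_scene_spec(acq, mural_density = mural_density,
                             fibroblast_density = fibroblast_density, seed = s)
    tr <- build_scene(sp)
    if (nrow(tr$cells) < 2L) next
    d <- as.matrix(stats::dist(tr$cells[, c("cz", "cy", "cx")]))
    diag(d) <- Inf
    if (all(d > 2 * max(tr$cells$nuc_along) + 1.5)) return(tr)
  }
  stop("no separated scene found in ", tries, " seeds")
}

# wrap bare channel arrays into the volume structure the quantify functions use
make_vol <- function(channels, acq) {
  structure(list(channels = channels, acquisition = acq,
                 condition = "sham-ipsi", region = "away"),
            class = "multichannel_volume")
}

# paint a filled disk into a matrix (pixel units)
paint_disk <- function(m, cy, cx, r, value = 1) {
  for (iy in seq_len(nrow(m))) for (ix in seq_len(ncol(m)))
    if ((iy - cy)^2 + (ix - cx)^2 <= r^2) m[iy, ix] <- value
  m
}
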