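# Independent brute-force oracles used across the suite. These recompute
# quantities from first principles and never call the code paths they
# check.

# Exhaustive Ward agglomeration from raw coordinates: at every step the
# total within-cluster sum of squares of every candidate merge is
# recomputed from scratch. Returns the merge sequence as leaf-set
# signatures plus the Ward (ward.D2-scale) heights sqrt(2 * delta_SSE).
oracle_ward <- function(x) {
  sse <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2L, colMeans(xs))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  sigs <- character(0)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq.int(i + 1L, length(clusters))) {
        d <- sse(c(clusters[[i]], clusters[[j]])) -
          sse(clusters[[i]]) - sse(clusters[[j]])
        if (is.null(best) || d < best$d) best <- list(i = i, j = j, d = d)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    sigs <- c(sigs, paste(merged, collapse = ","))
    heights <- c(heights, sqrt(2 * best$d))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(signatures = sigs, heights = heights)
}

# Leaf-set signature of every merge step of an hclust tree, in merge
# order.
hclust_signatures <- function(tree) {
  n <- length(tree$order)
  members <- vector("list", nrow(tree$merge))
  sigs <- character(nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    take <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(take(tree$merge[k, 1L]),
                           take(tree$merge[k, 2L])))
    sigs[k] <- paste(members[[k]], collapse = ",")
  }
  sigs
}

# Adjusted Rand index by explicit pair counting over all item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  np <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / np
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(1)
  (s11 - expected) / (maxidx - expected)
}

# High-resolution quadrature oracle for the adsorption free energy of an
# analytic PMF: same Boltzmann-average definition, trapezoid on a grid
# `refine` times finer, W evaluated analytically.
oracle_dg <- function(Wfun, layer_start, delta = 0.8, kBT = 2.49433863,
                      refine = 100L, base_step = 0.002) {
  ss <- seq(layer_start, layer_start + delta,
            length.out = refine * round(delta / base_step) + 1L)
  f <- exp(-Wfun(ss) / kBT)
  dx <- diff(ss)
  I <- sum(dx * (f[-1L] + f[-length(f)]) / 2)
  -kBT * log(I / (ss[length(ss)] - ss[1L]))
}

# Small default synthetic study used in several files.
default_sim <- function(seed = 1L) generate_matrix(synthetic_config(seed = seed))
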