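# Independent brute-force oracles, written directly from the defining
# formulas and kept free of any package code paths.

oracle_hudson <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(NA_real_)
  num / den
}

# Weir & Cockerham (1984) two-population variance components, diploid,
# heterozygosity at Hardy-Weinberg expectation; scalar transliteration.
oracle_wc <- function(p1, n1_dip, p2, n2_dip) {
  h1 <- 2 * p1 * (1 - p1)
  h2 <- 2 * p2 * (1 - p2)
  nbar <- (n1_dip + n2_dip) / 2
  nc <- (2 * nbar - (n1_dip^2 + n2_dip^2) / (2 * nbar)) / 1
  pbar <- (n1_dip * p1 + n2_dip * p2) / (2 * nbar)
  s2 <- (n1_dip * (p1 - pbar)^2 + n2_dip * (p2 - pbar)^2) / nbar
  hbar <- (n1_dip * h1 + n2_dip * h2) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# r2 from explicit two-locus haplotype class counts.
oracle_r2 <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  pA <- sum(x == 1) / n
  pB <- sum(y == 1) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

all_bit_strings <- function(len) {
  apply(expand.grid(rep(list(0:1), len)), 1, paste0, collapse = "")
}

hamming_str <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Exhaustively find the minimum achievable summed Hamming distance from
# one string to a triple.
oracle_min_triple_cost <- function(a, b, c) {
  min(vapply(all_bit_strings(nchar(a)), function(s) {
    hamming_str(s, a) + hamming_str(s, b) + hamming_str(s, c)
  }, numeric(1)))
}

mst_length_matrix <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  total <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    total <- total + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, D[v, ])
  }
  unname(total)
}

# Minimal Steiner tree length over Hamming space for <= 4 terminals:
# at most k - 2 Steiner points of degree >= 3 are needed in a metric
# space, so enumerate 0, 1 or 2 extra strings and take the shortest MST.
oracle_steiner_length <- function(terminals) {
  len <- nchar(terminals[1])
  universe <- all_bit_strings(len)
  dmat <- function(strs) {
    m <- do.call(rbind, lapply(strs, function(s) as.integer(strsplit(s, "")[[1]])))
    as.matrix(dist(m, method = "manhattan"))
  }
  best <- mst_length_matrix(dmat(terminals))
  max_extra <- max(0, length(terminals) - 2)
  if (max_extra >= 1) {
    for (s1 in universe) {
      l1 <- mst_length_matrix(dmat(c(terminals, s1)))
      if (l1 < best) best <- l1
    }
  }
  if (max_extra >= 2) {
    for (i in seq_along(universe)) {
      for (j in seq_len(i - 1)) {
        l2 <- mst_length_matrix(dmat(c(terminals, universe[i], universe[j])))
        if (l2 < best) best <- l2
      }
    }
  }
  best
}

# Minimum Steiner tree length connecting the given terminal vertices
# within a weighted graph (Dreyfus-Wagner over <= 4 terminals).
graph_steiner_length <- function(n, edges, terminals) {
  inf <- Inf
  d <- matrix(inf, n, n)
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; w <- edges$weight[k]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- d[i, j]
  }
  for (via in seq_len(n)) {
    d <- pmin(d, outer(d[, via], d[via, ], `+`))
  }
  k <- length(terminals)
  if (k == 1) return(0)
  n_sub <- bitwShiftL(1L, k) - 1L
  dp <- matrix(inf, nrow = n_sub, ncol = n)
  for (t in seq_len(k)) {
    dp[bitwShiftL(1L, t - 1L), ] <- d[terminals[t], ]
  }
  for (S in seq_len(n_sub)) {
    if (sum(bitwAnd(S, bitwShiftL(1L, seq_len(k) - 1L)) > 0) < 2) next
    # combine sub-splits
    sub <- bitwAnd(S - 1L, S)
    while (sub > 0) {
      dp[S, ] <- pmin(dp[S, ], dp[sub, ] + dp[S - sub, ])
      sub <- bitwAnd(sub - 1L, S)
    }
    # relax through the metric closure
    for (v in seq_len(n)) {
      dp[S, ] <- pmin(dp[S, ], dp[S, v] + d[v, ])
    }
  }
  min(dp[n_sub, ])
}
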