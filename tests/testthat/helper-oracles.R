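# Independent oracles used by the tests. These are written directly from the
# definitions (scoring scheme, closed forms, brute force) and share no code
# with the package implementation paths they check.

# Affine-gap global alignment score by memoised recursion over the
# (i, j, state) graph, states: M = last column was a substitution,
# X = gap in b (deletion), Y = gap in a (insertion).
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- -gap_open - gap_extend * (i - 1)
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- -gap_open - gap_extend * (j - 1)
  }
  for (i in seq_len(n + 1)) {
    for (j in seq_len(m + 1)) {
      if (i > 1 && j > 1) {
        s <- if (av[i - 1] == bv[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      }
      if (i > 1 && (i > 2 || j > 1)) {
        X[i, j] <- max(X[i, j], M[i - 1, j] - gap_open - gap_extend,
                       X[i - 1, j] - gap_extend,
                       Y[i - 1, j] - gap_open - gap_extend)
      }
      if (j > 1 && (j > 2 || i > 1)) {
        Y[i, j] <- max(Y[i, j], M[i, j - 1] - gap_open - gap_extend,
                       Y[i, j - 1] - gap_extend,
                       X[i, j - 1] - gap_open - gap_extend)
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Closed-form K2P evaluator from transition/transversion proportions.
oracle_k2p <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

# Count P and Q of two equal-length gap-free sequences by explicit base-pair
# lookup (purine/pyrimidine table), independent of the package counters.
oracle_pq <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- av != bv
  ts <- diff & purine[av] == purine[bv]
  list(P = sum(ts) / length(av), Q = sum(diff & !ts) / length(av),
       n = length(av))
}

# Brute-force union-find over an edge list; returns a canonical component
# label per node (smallest member id).
oracle_components <- function(nodes, from, to) {
  comp <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (comp[[x]] != x) x <- comp[[x]]
    x
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) comp[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  # canonical label: smallest node id in each component
  canon <- tapply(nodes, roots, min)
  stats::setNames(unname(canon[roots]), nodes)
}

# Brute-force per-base interval coverage fraction of [start, end] by a set of
# intervals (all 1-based inclusive).
oracle_coverage <- function(start, end, iv_start, iv_end) {
  pos <- start:end
  covered <- rep(FALSE, length(pos))
  for (k in seq_along(iv_start)) {
    covered <- covered | (pos >= iv_start[k] & pos <= iv_end[k])
  }
  mean(covered)
}

# Random mutated copy of a sequence: substitutions only, at given per-site
# probability (any different base, uniform).
mutate_subs <- function(seq, p) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < p)
  for (i in hit) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
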