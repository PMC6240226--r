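# Independent oracles, written in plain R against the same scoring
# conventions as the package but sharing no code with it.

# global alignment score, affine gaps (gap of length g costs open + g*ext)
nw_oracle <- function(a, b, match = 1, mismatch = -1,
                      gap_open = -4, gap_ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(m)) X[i + 1, 1] <- gap_open + i * gap_ext
  for (j in seq_len(n)) Y[1, j + 1] <- gap_open + j * gap_ext
  s <- function(x, y) if (x %in% c("A","C","G","T") && x == y) match else mismatch
  for (i in seq_len(m)) for (j in seq_len(n)) {
    h <- max(M[i, j], X[i, j], Y[i, j])
    M[i + 1, j + 1] <- h + s(A[i], B[j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_ext,
                           Y[i, j + 1] + gap_open + gap_ext,
                           X[i, j + 1] + gap_ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_ext,
                           X[i + 1, j] + gap_open + gap_ext,
                           Y[i + 1, j] + gap_ext)
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# local alignment score (Smith-Waterman), affine gaps
sw_oracle <- function(a, b, match = 1, mismatch = -1,
                      gap_open = -4, gap_ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e15
  H <- matrix(0, m + 1, n + 1); E <- matrix(NEG, m + 1, n + 1); F <- E
  s <- function(x, y) if (x %in% c("A","C","G","T") && x == y) match else mismatch
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_ext,
                           E[i + 1, j] + gap_ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_ext,
                           F[i, j + 1] + gap_ext)
    h <- max(0, H[i, j] + s(A[i], B[j]), E[i + 1, j + 1], F[i + 1, j + 1])
    H[i + 1, j + 1] <- h
    best <- max(best, h)
  }
  best
}

# percent p-distance by direct column counting (pairwise deletion, N excluded)
pdist_oracle <- function(r1, r2) {
  a <- strsplit(r1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  ok <- a %in% c("A","C","G","T") & b %in% c("A","C","G","T")
  if (!any(ok)) return(NA_real_)
  100 * sum(a[ok] != b[ok]) / sum(ok)
}

# connected components by breadth-first transitive closure
components_oracle <- function(ids, edges) {
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  for (v in ids) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- k
      queue <- c(queue, setdiff(adj[[u]], names(comp)[!is.na(comp)]))
    }
  }
  comp
}

# Karlin-Altschul E-value matching the built-in engine defaults
evalue_oracle <- function(score, m, n, K = 0.13, lambda = 0.318) {
  K * m * n * exp(-lambda * score)
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

# substitute exactly k positions (to a different base)
mutate_k <- function(seq, k, positions = NULL) {
  x <- strsplit(seq, "")[[1]]
  pos <- if (is.null(positions)) sample(length(x), k) else positions
  for (p in pos) x[p] <- sample(setdiff(c("A","C","G","T"), x[p]), 1)
  paste(x, collapse = "")
}

# random pair of gapped alignment rows of equal length
random_gapped_pair <- function(len = 60) {
  alph <- c("A","C","G","T","N","-")
  w <- c(5, 5, 5, 5, 1, 3)
  r1 <- paste(sample(alph, len, TRUE, prob = w), collapse = "")
  r2 <- paste(sample(alph, len, TRUE, prob = w), collapse = "")
  c(r1, r2)
}
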