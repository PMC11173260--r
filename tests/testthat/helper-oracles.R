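# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

# Global alignment score by plain dynamic programming with linear gap
# costs (match/mismatch scoring). Independent of the package's aligner.
oracleAlignScore <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  n <- length(ca); m <- length(cb)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- gap * (0:n)
  D[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      D[i + 1L, j + 1L] <- max(D[i, j] + s, D[i, j + 1L] + gap,
                               D[i + 1L, j] + gap)
    }
  }
  D[n + 1L, m + 1L]
}

# dipeptide counts by explicit window enumeration
oracleDipeptideCounts <- function(seq) {
  n <- nchar(seq)
  pairs <- vapply(seq_len(n - 1L), function(i) substr(seq, i, i + 1L), "")
  table(pairs)
}

# amino-acid counts by explicit enumeration
oracleAACounts <- function(seq) {
  table(strsplit(seq, "")[[1L]])
}

# connected components by boolean reachability closure
oracleComponents <- function(nodes, edgePairs) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  if (length(edgePairs)) {
    for (e in edgePairs) {
      A[e[1L], e[2L]] <- TRUE
      A[e[2L], e[1L]] <- TRUE
    }
  }
  repeat {
    R <- (A %*% A) > 0
    if (identical(R, A)) break
    A <- R
  }
  comps <- unique(apply(A, 1L, function(row) paste(sort(nodes[row]),
                                                   collapse = ",")))
  comps <- lapply(strsplit(comps, ","), identity)
  comps[order(vapply(comps, `[`, "", 1L))]
}

# random canonical-residue sequence
randomSeq <- function(len) {
  paste(sample(enzTopt::AA_CANONICAL, len, replace = TRUE), collapse = "")
}

# small labeled fixture set with controllable rare/normal composition
labeledFixture <- function(nRare = 2L, nNormal = 10L, seed = 42L) {
  set.seed(seed)
  n <- nRare + nNormal
  y <- c(stats::runif(nRare, 5, 15), stats::runif(nNormal, 30, 55))
  X <- matrix(stats::rnorm(n * 3L), n, 3L,
              dimnames = list(sprintf("r%02d", seq_len(n)), NULL))
  list(X = X, y = y)
}
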