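# Internal helpers shared across modules.

# Collapse a V/J call to gene level: strip the allele suffix after '*' and,
# for ambiguous multi-gene calls, keep the first comma-separated gene.
geneLevel <- function(call) {
  sub("\\*.*$", "", sub(",.*$", "", call))
}

# Union-find with path compression; `edges` is a 2-column integer matrix of
# indices into 1..n. Returns component labels renumbered 1..k in order of
# first appearance.
ufComponents <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Character matrix (one row per sequence) for equal-length sequences.
charMatrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) <= 1L)
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

# Pairwise fraction-identical matrix for equal-length strings. Position-wise
# equality; 'X' (or 'N') only matches itself.
identityMatrix <- function(seqs) {
  m <- length(seqs)
  if (m == 1L) return(matrix(1, 1, 1))
  ch <- charMatrix(seqs)
  L <- ncol(ch)
  eq <- matrix(0L, m, m)
  for (p in seq_len(L)) eq <- eq + outer(ch[, p], ch[, p], "==")
  eq / L
}

# Pairwise Hamming distance matrix for equal-length strings.
hammingMatrix <- function(seqs) {
  m <- length(seqs)
  L <- nchar(seqs[1L])
  round((1 - identityMatrix(seqs)) * L)
}

# Hamming distance between two equal-length strings, optionally ignoring
# positions where either carries 'N'. Returns c(mismatches, compared).
hammingCompared <- function(a, b, ignore_n = TRUE) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  keep <- if (ignore_n) ca != "N" & cb != "N" else rep(TRUE, length(ca))
  c(sum(ca[keep] != cb[keep]), sum(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic RNG scope: seeds locally, restores the caller's RNG state.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
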