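# Brute-force oracles and fixture builders, independent of the package's
# clustering path: plain all-pairs graphs, BFS components, per-position
# majority with explicit tie rules.

makeRecords <- function(cdr3_nt, v_call = "IGHV1-1", j_call = "IGHJ1",
                        copies = 1L, mouse_id = "m1", strain = "WT",
                        subset = "FoB", replicate = 1L,
                        cdr3_aa = NULL, v_observed_nt = NA_character_,
                        v_mutation_count = NA_integer_, functional = NA,
                        record_id = NULL) {
  n <- length(cdr3_nt)
  if (is.null(cdr3_aa)) {
    cdr3_aa <- rep(NA_character_, n)
    inframe <- nchar(cdr3_nt) %% 3L == 0L
    cdr3_aa[inframe] <- translateCdr3(cdr3_nt[inframe])
  }
  data.frame(
    record_id = record_id %||% sprintf("r%03d", seq_len(n)),
    mouse_id = rep_len(mouse_id, n), strain = rep_len(strain, n),
    subset = rep_len(subset, n), replicate = rep_len(as.integer(replicate), n),
    v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
    cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
    copies = rep_len(as.integer(copies), n),
    v_observed_nt = rep_len(v_observed_nt, n),
    v_mutation_count = rep_len(as.integer(v_mutation_count), n),
    functional = rep_len(functional, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BFS connected components of a boolean adjacency matrix.
bfsComponents <- function(adj) {
  n <- nrow(adj)
  lab <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(lab[i])) next
    k <- k + 1L
    frontier <- i
    lab[i] <- k
    while (length(frontier)) {
      nb <- which(adj[frontier[1L], ] & is.na(lab))
      lab[nb] <- k
      frontier <- c(frontier[-1L], nb)
    }
  }
  lab
}

oracleIdentity <- function(a, b) {
  mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
}

oracleHamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

oracleGene <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))

# Copy-weighted per-position majority; ties A<C<G<T, N only on strict win.
oracleConsensus <- function(seqs, copies) {
  L <- nchar(seqs[1L])
  out <- character(L)
  for (p in seq_len(L)) {
    ch <- substr(seqs, p, p)
    score <- sapply(c("A", "C", "G", "T"), function(b) sum(copies[ch == b]))
    n_score <- sum(copies[ch == "N"])
    best <- c("A", "C", "G", "T")[which.max(score)]
    out[p] <- if (n_score > max(score)) "N" else best
  }
  paste(out, collapse = "")
}

# Exhaustive two-stage clustering: all-pairs identity graph within the
# (mouse, V gene, J gene, CDR3 length) partition, BFS components, then
# repeated all-pairs consensus-Hamming collapse until stable.
oracleClones <- function(rec, threshold = 0.85, max_nt_dist = 2,
                         collapse = TRUE) {
  n <- nrow(rec)
  vg <- oracleGene(rec$v_call); jg <- oracleGene(rec$j_call)
  len <- nchar(rec$cdr3_nt)
  aa <- rec$cdr3_aa
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (jx in seq_len(n)) {
    adj[i, jx] <- rec$mouse_id[i] == rec$mouse_id[jx] &&
      vg[i] == vg[jx] && jg[i] == jg[jx] && len[i] == len[jx] &&
      oracleIdentity(aa[i], aa[jx]) >= threshold
  }
  lab <- bfsComponents(adj)
  if (collapse) {
    repeat {
      k <- max(lab)
      cons <- vapply(seq_len(k), function(c)
        oracleConsensus(rec$cdr3_nt[lab == c], rec$copies[lab == c]),
        character(1))
      cmouse <- vapply(seq_len(k), function(c) rec$mouse_id[lab == c][1L],
                       character(1))
      cadj <- matrix(FALSE, k, k)
      for (i in seq_len(k)) for (jx in seq_len(k)) {
        cadj[i, jx] <- cmouse[i] == cmouse[jx] &&
          nchar(cons[i]) == nchar(cons[jx]) &&
          oracleHamming(cons[i], cons[jx]) <= max_nt_dist
      }
      clab <- bfsComponents(cadj)
      if (max(clab) == k) break
      lab <- clab[lab]
    }
  }
  lab
}

# Canonical signature of a partition over record ids, for equality up to
# label permutation.
partitionSignature <- function(record_ids, labels) {
  groups <- split(record_ids, labels)
  groups <- vapply(groups, function(g) paste(sort(g), collapse = ","),
                   character(1))
  paste(sort(groups), collapse = ";")
}

cloneSetSignature <- function(cs) {
  rec <- cloneRecords(cs)
  partitionSignature(rec$record_id, rec$clone_id)
}

# Random small clustering instance with borderline identities, shared
# founders (collapse candidates) and occasional V miscalls.
randomInstance <- function(seed) {
  set.seed(seed)
  n <- sample(2:12, 1L)
  n_founders <- sample(1:4, 1L)
  aa_len <- sample(c(6L, 7L, 8L), 1L)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  founders <- vapply(seq_len(n_founders), function(i)
    paste(sample(codons, aa_len, replace = TRUE), collapse = ""),
    character(1))
  f <- sample(n_founders, n, replace = TRUE)
  cdr3 <- vapply(founders[f], function(s) {
    ch <- strsplit(s, "")[[1L]]
    mut <- which(runif(length(ch)) < 0.08)
    for (p in mut) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  v_pool <- c("IGHV1-1*01", "IGHV1-2", "IGHV2-1*02,IGHV2-1*03")
  makeRecords(cdr3,
              v_call = sample(v_pool, n, replace = TRUE),
              j_call = sample(c("IGHJ1", "IGHJ2"), n, replace = TRUE),
              copies = sample(1:5, n, replace = TRUE),
              mouse_id = sample(c("m1", "m1", "m2"), n, replace = TRUE),
              subset = sample(ighSubsets(), n, replace = TRUE),
              replicate = sample(1:2, n, replace = TRUE),
              functional = TRUE)
}

# Pair-counting adjusted Rand index, straight from the contingency table.
oracleAri <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(sum(tab))
  expected <- sum_i * sum_j / total
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
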