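# Per-subset repertoire summary statistics: D20 clonality index, replicate
# Jaccard overlap, somatic hypermutation, CDR3 lengths, VH usage.

#' D20 clonality index
#'
#' Fraction of total sequence copies contributed by the 20 largest clones:
#' copies are sorted in decreasing order (stable, so boundary ties resolve by
#' the caller's clone order) and the top \code{min(20, n)} are summed and
#' divided by the total.
#'
#' @param clone_copies Numeric vector of per-clone copy counts (>= 1 each).
#' @param top Number of top-ranked clones to sum (default 20).
#' @return Fraction in (0, 1].
#' @examples
#' d20Index(c(50, rep(10, 9), rep(1, 30)))  # 150/170
#' @export
d20Index <- function(clone_copies, top = 20L) {
  if (!length(clone_copies)) stop("d20Index of an empty clone list is undefined")
  if (any(is.na(clone_copies)) || any(clone_copies < 1))
    stop("clone_copies must be >= 1")
  s <- sort(clone_copies, decreasing = TRUE, method = "radix")
  sum(s[seq_len(min(top, length(s)))]) / sum(s)
}

#' Replicate-library Jaccard overlap
#'
#' Jaccard index between the clone sets recovered from two replicate
#' libraries of the same sorted sample: each clone counts once, with no
#' weighting for clone size.
#'
#' @param clone_ids_rep1,clone_ids_rep2 Vectors of clone identifiers.
#' @return \code{|intersection| / |union|}; 0 (with a warning) when both sets
#'   are empty.
#' @examples
#' replicateJaccard(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
#' @export
replicateJaccard <- function(clone_ids_rep1, clone_ids_rep2) {
  a <- unique(clone_ids_rep1)
  b <- unique(clone_ids_rep2)
  if (!length(a) && !length(b)) {
    warning("both replicate clone sets are empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Replicate overlap for every sorted sample
#'
#' Computes \code{\link{replicateJaccard}} between the two replicate
#' libraries of each (mouse, subset) sample in a clone set.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @return \code{data.frame(mouse_id, strain, subset, jaccard, n_clones)}.
#' @export
replicateOverlap <- function(clone_set) {
  pres <- clonePresence(clone_set)
  key <- interaction(pres$mouse_id, pres$subset, drop = TRUE)
  rows <- lapply(split(pres, key), function(p) {
    ids1 <- p$clone_id[p$replicate == 1L]
    ids2 <- p$clone_id[p$replicate == 2L]
    data.frame(mouse_id = p$mouse_id[1L], strain = p$strain[1L],
               subset = p$subset[1L],
               jaccard = replicateJaccard(ids1, ids2),
               n_clones = length(unique(p$clone_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mouse_id, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-record V-segment mutation percent: 100 * mutated / compared positions.
# Uses v_mutation_count when present (denominator = germline V length),
# otherwise the Hamming distance between the germline-aligned V segment and
# the same-length germline slice, ignoring N positions.
recordMutationPercent <- function(records, germlines) {
  n <- nrow(records)
  pct <- rep(NA_real_, n)
  vseg <- vSegments(germlines)
  glen <- stats::setNames(Biostrings::width(vseg), names(vseg))
  gseq <- stats::setNames(as.character(vseg), names(vseg))
  vg <- geneLevel(records$v_call)
  has_count <- !is.na(records$v_mutation_count)
  if (any(has_count)) {
    denom <- glen[vg[has_count]]
    if (anyNA(denom))
      stop("germline V segment missing for: ",
           paste(unique(vg[has_count][is.na(denom)]), collapse = ", "))
    pct[has_count] <- 100 * records$v_mutation_count[has_count] / denom
  }
  need_seq <- !has_count & !is.na(records$v_observed_nt)
  for (i in which(need_seq)) {
    g <- gseq[vg[i]]
    if (is.na(g))
      stop("germline V segment missing for: ", vg[i])
    obs <- records$v_observed_nt[i]
    slice <- substr(g, 1L, nchar(obs))
    if (nchar(slice) < nchar(obs))
      stop("germline V slice shorter than observed segment for ", vg[i])
    hc <- hammingCompared(obs, slice)
    pct[i] <- if (hc[2L] > 0) 100 * hc[1L] / hc[2L] else NA_real_
  }
  pct
}

#' Somatic hypermutation per clone and subset
#'
#' Copy-weighted mean V-segment mutation percent of each clone, recomputed
#' separately for each subset the clone appears in (a clone overlapping
#' several subsets gets one value per subset, from that subset's sequences
#' only).
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param germlines A \linkS4class{GermlineSet} used for mutation counting.
#' @return \code{data.frame(clone_id, mouse_id, strain, subset, copies,
#'   shm_percent)}.
#' @export
shmByCloneSubset <- function(clone_set, germlines) {
  rec <- cloneRecords(clone_set)
  pct <- recordMutationPercent(rec, germlines)
  if (anyNA(pct)) {
    bad <- unique(rec$clone_id[is.na(pct)])
    stop("mutation count unresolvable (no v_mutation_count or v_observed_nt)",
         " for clone(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(rec$clone_id, rec$subset, sep = "\r")
  rows <- lapply(split(seq_len(nrow(rec)), key), function(ix) {
    w <- rec$copies[ix]
    data.frame(clone_id = rec$clone_id[ix[1L]],
               mouse_id = rec$mouse_id[ix[1L]],
               strain = rec$strain[ix[1L]], subset = rec$subset[ix[1L]],
               copies = sum(w),
               shm_percent = sum(pct[ix] * w) / sum(w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$clone_id, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutation percent of one clone in one subset
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param clone_id Clone identifier.
#' @param subset Subset label; the clone must have members in it.
#' @param germlines A \linkS4class{GermlineSet}.
#' @return Copy-weighted mean mutation percent (>= 0).
#' @export
cloneMutationPercent <- function(clone_set, clone_id, subset, germlines) {
  rec <- cloneRecords(clone_set)
  ix <- rec$clone_id == clone_id & rec$subset == subset
  if (!any(ix))
    stop("clone ", clone_id, " has no members in subset ", subset)
  sub <- rec[ix, , drop = FALSE]
  pct <- recordMutationPercent(sub, germlines)
  if (anyNA(pct))
    stop("mutation count unresolvable for clone ", clone_id)
  sum(pct * sub$copies) / sum(sub$copies)
}

#' Fraction of clones with somatic hypermutation
#'
#' Fraction of a stratum's clones whose per-subset mutation percent is at or
#' above \code{mutated_threshold_percent}. Each clone counts once per subset.
#' Weighted mode weights each clone by its subset copy count instead.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param germlines A \linkS4class{GermlineSet}.
#' @param subset Subset label (required).
#' @param strain Optional strain restriction; default aggregates all strains.
#' @param mutated_threshold_percent Percent of compared V positions at or
#'   above which a clone counts as mutated; default 1 (buffers sequencing
#'   error; 0 counts any mutated clone).
#' @param weighted Weight clones by subset copy count (default FALSE).
#' @return Fraction in [0, 1].
#' @export
shmFraction <- function(clone_set, germlines, subset, strain = NULL,
                        mutated_threshold_percent = 1.0, weighted = FALSE) {
  shm <- shmByCloneSubset(clone_set, germlines)
  shm <- shm[shm$subset == subset, , drop = FALSE]
  if (!is.null(strain)) shm <- shm[shm$strain %in% strain, , drop = FALSE]
  if (!nrow(shm))
    stop("no clones in stratum (subset=", subset,
         if (!is.null(strain)) paste0(", strain=", paste(strain, collapse = "/")),
         ")")
  mutated <- shm$shm_percent >= mutated_threshold_percent
  if (weighted) sum(shm$copies[mutated]) / sum(shm$copies)
  else mean(mutated)
}

#' CDR3 length distribution by stratum
#'
#' One CDR3 nucleotide length entry per clone per (strain, subset)
#' combination it appears in.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @return Long \code{data.frame(strain, subset, clone_id, cdr3_len_nt)}.
#' @export
cdr3LengthDistribution <- function(clone_set) {
  pres <- clonePresence(clone_set)
  strat <- unique(pres[, c("clone_id", "strain", "subset")])
  cl <- clones(clone_set)
  strat$cdr3_len_nt <- cl$cdr3_len_nt[match(strat$clone_id, cl$clone_id)]
  out <- strat[order(strat$strain, strat$subset, strat$clone_id),
               c("strain", "subset", "clone_id", "cdr3_len_nt")]
  rownames(out) <- NULL
  out
}

#' VH gene usage matrix
#'
#' Clone counts per V gene per (strain, subset) stratum, each clone counted
#' once per stratum; the \code{top_n} genes by total clone count are kept
#' (lexicographic tie-break) and each gene row is min-max normalized to
#' [0, 1]. Constant rows map to 0 and are flagged.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param top_n Number of most-used genes to keep; default 20.
#' @return List with \code{counts} (integer matrix gene x stratum),
#'   \code{normalized} (same shape, row min-max), and \code{constant_rows}
#'   (logical vector flagging degenerate rows).
#' @export
vhUsageMatrix <- function(clone_set, top_n = 20L) {
  if (!nClones(clone_set)) stop("clone set is empty")
  pres <- clonePresence(clone_set)
  strat <- unique(pres[, c("clone_id", "strain", "subset")])
  cl <- clones(clone_set)
  strat$gene <- cl$v_call[match(strat$clone_id, cl$clone_id)]
  strat$stratum <- paste(strat$strain, strat$subset, sep = ".")
  counts <- table(strat$gene, strat$stratum)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  totals <- rowSums(counts)
  if (nrow(counts) < top_n)
    warning("only ", nrow(counts), " distinct V genes present (top_n = ",
            top_n, "); returning all")
  keep <- order(-totals, rownames(counts))[seq_len(min(top_n, nrow(counts)))]
  counts <- counts[keep, , drop = FALSE]
  rng <- apply(counts, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  constant <- span == 0
  norm <- (counts - rng[1L, ]) / ifelse(constant, 1, span)
  norm[constant, ] <- 0
  list(counts = counts, normalized = norm, constant_rows = constant)
}

#' D20 per sorted sample
#'
#' D20 index of each (mouse, subset) sample, computed on the clone copy
#' totals of that sample (replicates merged).
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param top Number of top clones; default 20.
#' @return \code{data.frame(mouse_id, strain, subset, d20, n_clones)}.
#' @export
d20BySample <- function(clone_set, top = 20L) {
  pres <- clonePresence(clone_set)
  agg <- stats::aggregate(copies ~ clone_id + mouse_id + strain + subset,
                          data = pres, FUN = sum)
  key <- interaction(agg$mouse_id, agg$subset, drop = TRUE)
  rows <- lapply(split(agg, key), function(p)
    data.frame(mouse_id = p$mouse_id[1L], strain = p$strain[1L],
               subset = p$subset[1L], d20 = d20Index(p$copies, top = top),
               n_clones = nrow(p), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$mouse_id, out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-stratum repertoire profile
#'
#' Convenience summary per (strain, subset): clone count, mean D20 across the
#' stratum's mice, mean replicate Jaccard, SHM fractions (when germlines are
#' supplied) and median CDR3 length.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param germlines Optional \linkS4class{GermlineSet}; adds SHM columns.
#' @param mutated_threshold_percent Passed to \code{\link{shmFraction}}.
#' @return \code{data.frame}, one row per (strain, subset).
#' @export
subsetProfiles <- function(clone_set, germlines = NULL,
                           mutated_threshold_percent = 1.0) {
  d20 <- d20BySample(clone_set)
  rj <- replicateOverlap(clone_set)
  len <- cdr3LengthDistribution(clone_set)
  shm <- if (!is.null(germlines)) shmByCloneSubset(clone_set, germlines)
  strata <- unique(d20[, c("strain", "subset")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    st <- strata$strain[i]; sb <- strata$subset[i]
    pick <- function(df) df[df$strain == st & df$subset == sb, , drop = FALSE]
    out <- data.frame(
      strain = st, subset = sb,
      n_clones = length(unique(pick(len)$clone_id)),
      d20_mean = mean(pick(d20)$d20),
      replicate_jaccard_mean = mean(pick(rj)$jaccard),
      cdr3_len_median = stats::median(pick(len)$cdr3_len_nt),
      stringsAsFactors = FALSE)
    if (!is.null(shm)) {
      s <- pick(shm)
      mut <- s$shm_percent >= mutated_threshold_percent
      out$shm_fraction_unweighted <- mean(mut)
      out$shm_fraction_weighted <- sum(s$copies[mut]) / sum(s$copies)
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$strain, match(out$subset, ighSubsets())), , drop = FALSE]
}
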