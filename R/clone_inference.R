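# Clone inference: two-stage grouping of IgH rearrangements.
#
# Stage 1 partitions records by (mouse, V gene, J gene, CDR3 nt length) and
# clusters each partition at >= `threshold` CDR3 amino-acid identity
# (single-linkage by default: connected components of the identity graph,
# which equals a hierarchical single-linkage dendrogram cut at the
# threshold). Stage 2 merges clones whose consensus CDR3 nucleotide
# sequences are within `max_nt_dist` (Hamming) of each other, crossing V/J
# call boundaries, to absorb erroneous gene calls. The merge is transitive
# and iterated to a fixed point so a second collapse is a no-op.

#' CDR3 amino-acid identity
#'
#' Fraction of positions with equal residues between two equal-length CDR3
#' amino-acid sequences. \code{X} (untranslatable codon) matches nothing
#' except \code{X}.
#'
#' @param aa1,aa2 Amino-acid strings of equal length >= 1.
#' @return Fraction in [0, 1].
#' @examples
#' cdr3Identity("CARDYW", "CARDFW")  # 5/6
#' @export
cdr3Identity <- function(aa1, aa2) {
  if (nchar(aa1) != nchar(aa2))
    stop("identity is only defined for equal-length CDR3 sequences")
  if (nchar(aa1) < 1L) stop("sequences must have length >= 1")
  a <- strsplit(aa1, "", fixed = TRUE)[[1L]]
  b <- strsplit(aa2, "", fixed = TRUE)[[1L]]
  mean(a == b)
}

# Cluster equal-length CDR3 amino-acid sequences at an identity threshold.
# Returns integer group labels parallel to `aa`.
clusterCdr3 <- function(aa, threshold = 0.85,
                        linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!length(aa)) return(integer())
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  u <- sort(unique(aa))
  ui <- match(aa, u)
  if (length(u) == 1L) return(rep(1L, length(aa)))
  idm <- identityMatrix(u)
  if (linkage == "single") {
    hits <- which(idm >= threshold & upper.tri(idm), arr.ind = TRUE)
    comp <- ufComponents(length(u), hits)
  } else {
    hc <- stats::hclust(stats::as.dist(1 - idm), method = "complete")
    comp <- stats::cutree(hc, h = 1 - threshold + 1e-9)
  }
  comp[ui]
}

#' Copy-weighted consensus CDR3
#'
#' Per-position copy-weighted majority base over equal-length CDR3 nucleotide
#' sequences. Ties break by fixed alphabet order A < C < G < T; \code{N} never
#' wins a tie against a concrete base.
#'
#' @param cdr3_nt Character vector of equal-length nucleotide sequences.
#' @param copies Integer copy weights (recycled if length 1).
#' @return Consensus nucleotide string.
#' @examples
#' consensusCdr3(c("AAA", "AAG"), copies = c(3, 1))  # "AAA"
#' @export
consensusCdr3 <- function(cdr3_nt, copies = 1L) {
  if (!length(cdr3_nt)) stop("consensus of an empty group is undefined")
  copies <- rep_len(as.numeric(copies), length(cdr3_nt))
  if (length(unique(cdr3_nt)) == 1L) return(cdr3_nt[1L])
  ch <- charMatrix(cdr3_nt)
  bases <- c("A", "C", "G", "T")
  apply_pos <- vapply(seq_len(ncol(ch)), function(p) {
    w <- vapply(bases, function(b) sum(copies[ch[, p] == b]), numeric(1))
    wn <- sum(copies[ch[, p] == "N"])
    best <- bases[which.max(w)]  # which.max takes the first => A<C<G<T ties
    if (wn > max(w)) "N" else best
  }, character(1))
  paste(apply_pos, collapse = "")
}

# Amino-acid sequences used for clustering: translated CDR3, or the
# translation of the in-frame prefix for frame-breaking lengths (consistent
# within a partition because partitions share the nt length).
clusteringAa <- function(rec) {
  aa <- rec$cdr3_aa
  na <- is.na(aa)
  if (any(na)) {
    trim <- substr(rec$cdr3_nt[na], 1L,
                   3L * (nchar(rec$cdr3_nt[na]) %/% 3L))
    aa[na] <- translateCdr3(trim)
  }
  aa
}

# One collapse pass over clone labels; returns the updated label vector or
# NULL when nothing merged. State vectors are indexed by compact label.
.collapsePass <- function(rec, lab, v, j, prov, max_nt_dist) {
  k <- max(lab)
  ix_by_clone <- split(seq_len(nrow(rec)), factor(lab, levels = seq_len(k)))
  cons <- vapply(ix_by_clone, function(ix)
    consensusCdr3(rec$cdr3_nt[ix], rec$copies[ix]), character(1))
  cop <- vapply(ix_by_clone, function(ix)
    sum(rec$copies[ix]), numeric(1))
  mouse <- vapply(ix_by_clone, function(ix) rec$mouse_id[ix[1L]], character(1))
  len <- nchar(cons)
  merged_any <- FALSE
  new_lab_of <- seq_len(k)
  for (g in split(seq_len(k), paste(mouse, len, sep = "\r"))) {
    if (length(g) < 2L) next
    d <- hammingMatrix(cons[g])
    hits <- which(d <= max_nt_dist & upper.tri(d), arr.ind = TRUE)
    if (!nrow(hits)) next
    comp <- ufComponents(length(g), hits)
    for (cset in split(seq_along(g), comp)) {
      if (length(cset) < 2L) next
      members <- g[cset]
      dom <- members[order(-cop[members], prov[members])][1L]
      new_lab_of[members] <- dom
      merged_any <- TRUE
    }
  }
  if (!merged_any) return(NULL)
  list(lab = new_lab_of[lab], v = v, j = j, prov = prov)
}

# Compact labels to 1..k preserving v/j/prov per clone.
.compactLabels <- function(lab, v, j, prov) {
  keep <- sort(unique(lab))
  remap <- match(lab, keep)
  list(lab = remap, v = v[keep], j = j[keep], prov = prov[keep])
}

# Assemble a CloneSet from records + final labels + per-clone v/j calls.
.buildCloneSet <- function(rec, lab, v, j, params) {
  k <- max(lab)
  ix_by_clone <- split(seq_len(nrow(rec)), factor(lab, levels = seq_len(k)))
  cons <- vapply(ix_by_clone, function(ix)
    consensusCdr3(rec$cdr3_nt[ix], rec$copies[ix]), character(1))
  cop <- vapply(ix_by_clone, function(ix)
    sum(rec$copies[ix]), numeric(1))
  mouse <- vapply(ix_by_clone, function(ix) rec$mouse_id[ix[1L]], character(1))
  strain <- vapply(ix_by_clone, function(ix) rec$strain[ix[1L]], character(1))
  nmem <- lengths(ix_by_clone)
  ord <- order(-cop, cons, v, j, mouse)
  clone_id_of <- integer(k)
  clone_id_of[ord] <- seq_len(k)
  len <- nchar(cons)
  aa <- rep(NA_character_, k)
  inframe <- len %% 3L == 0L
  if (any(inframe)) aa[inframe] <- translateCdr3(cons[inframe])
  clones <- data.frame(
    clone_id = clone_id_of, mouse_id = mouse, strain = strain,
    v_call = v, j_call = j, cdr3_len_nt = len,
    consensus_cdr3_nt = cons, consensus_cdr3_aa = aa,
    n_members = as.integer(nmem), total_copies = as.integer(cop),
    stringsAsFactors = FALSE
  )
  clones <- clones[order(clones$clone_id), , drop = FALSE]
  rownames(clones) <- NULL
  rec$clone_id <- clone_id_of[lab]
  methods::new("CloneSet", clones = clones, records = rec, params = params)
}

#' Infer clones from annotated rearrangements
#'
#' Groups rearrangements into clones per mouse: records sharing V gene, J
#' gene and CDR3 nucleotide length are clustered at \code{threshold} CDR3
#' amino-acid identity (single-linkage: connected components of the
#' >=threshold identity graph), then clones whose copy-weighted consensus
#' CDR3 nucleotide sequences lie within \code{max_nt_dist} (Hamming, equal
#' lengths only) are merged regardless of V/J call, absorbing erroneous gene
#' calls. The merged clone takes the V/J calls of its largest pre-merge
#' member; the consensus is recomputed over the merged membership and the
#' merge is repeated until stable. Clones are numbered by descending total
#' copies (ties by consensus string), so the output is invariant to input
#' order.
#'
#' @param records Canonical record \code{data.frame}
#'   (\code{\link{readAirrTsv}} or \code{\link{simulateRepertoire}}).
#' @param threshold CDR3 amino-acid identity floor for co-clustering
#'   (inclusive); default 0.85.
#' @param max_nt_dist Consensus CDR3 Hamming distance at or below which
#'   clones are collapsed; default 2.
#' @param linkage \code{"single"} (default) or \code{"complete"} linkage for
#'   the identity clustering.
#' @param collapse Set \code{FALSE} to skip the consensus-collapse stage.
#' @return A \linkS4class{CloneSet}.
#' @examples
#' sim <- simulateRepertoire(simConfig(seed = 1, n_mice_per_strain = 1,
#'                                     strains = "WT", n_clones = 20,
#'                                     copies_total = 200))
#' cs <- callClones(sim$records)
#' nClones(cs)
#' @export
callClones <- function(records, threshold = 0.85, max_nt_dist = 2,
                       linkage = c("single", "complete"), collapse = TRUE) {
  linkage <- match.arg(linkage)
  validateRecords(records)
  if (!nrow(records)) stop("cannot call clones on zero records")
  rec <- records
  attr(rec, "skip_report") <- NULL
  rownames(rec) <- NULL
  rec$v_call <- geneLevel(rec$v_call)
  rec$j_call <- geneLevel(rec$j_call)
  aa <- clusteringAa(rec)
  part <- paste(rec$mouse_id, rec$v_call, rec$j_call, nchar(rec$cdr3_nt),
                sep = "\r")
  lab <- integer(nrow(rec))
  v <- character(); j <- character()
  next_id <- 0L
  for (ix in split(seq_len(nrow(rec)), part)) {
    gl <- clusterCdr3(aa[ix], threshold, linkage)
    lab[ix] <- next_id + gl
    ng <- max(gl)
    v <- c(v, rep(rec$v_call[ix[1L]], ng))
    j <- c(j, rep(rec$j_call[ix[1L]], ng))
    next_id <- next_id + ng
  }
  params <- list(threshold = threshold, max_nt_dist = max_nt_dist,
                 linkage = linkage, collapse = collapse)
  st <- list(lab = lab, v = v, j = j, prov = .provisionalIds(rec, lab))
  if (collapse)
    st <- .collapseToFixedPoint(rec, st, max_nt_dist)
  .buildCloneSet(rec, st$lab, st$v, st$j, params)
}

# Canonical provisional ids (desc copies, consensus, v-call, j-call) used for
# deterministic dominant-clone tie-breaks during collapse.
.provisionalIds <- function(rec, lab) {
  k <- max(lab)
  ix_by_clone <- split(seq_len(nrow(rec)), factor(lab, levels = seq_len(k)))
  cons <- vapply(ix_by_clone, function(ix)
    consensusCdr3(rec$cdr3_nt[ix], rec$copies[ix]), character(1))
  cop <- vapply(ix_by_clone, function(ix) sum(rec$copies[ix]), numeric(1))
  vv <- vapply(ix_by_clone, function(ix) rec$v_call[ix[1L]], character(1))
  jj <- vapply(ix_by_clone, function(ix) rec$j_call[ix[1L]], character(1))
  prov <- integer(k)
  prov[order(-cop, cons, vv, jj)] <- seq_len(k)
  prov
}

.collapseToFixedPoint <- function(rec, st, max_nt_dist) {
  repeat {
    res <- .collapsePass(rec, st$lab, st$v, st$j, st$prov, max_nt_dist)
    if (is.null(res)) return(st)
    st <- .compactLabels(res$lab, res$v, res$j, res$prov)
  }
}

#' Collapse near-identical consensus clones in an existing CloneSet
#'
#' Re-applies the consensus-collapse stage: clones of the same mouse and CDR3
#' length whose consensus CDR3 nucleotide sequences are within
#' \code{max_nt_dist} (Hamming) are merged transitively, ignoring V/J call
#' differences. Idempotent: applying it to an already collapsed set returns
#' an identical set.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param max_nt_dist Hamming distance threshold in nucleotides; default 2.
#' @return A \linkS4class{CloneSet}.
#' @export
collapseClones <- function(clone_set, max_nt_dist = 2) {
  stopifnot(methods::is(clone_set, "CloneSet"))
  rec <- cloneRecords(clone_set)
  cl <- clones(clone_set)
  lab <- match(rec$clone_id, cl$clone_id)
  rec$clone_id <- NULL
  st <- list(lab = lab, v = cl$v_call, j = cl$j_call,
             prov = .provisionalIds(rec, lab))
  st <- .collapseToFixedPoint(rec, st, max_nt_dist)
  params <- cloneParams(clone_set)
  params$max_nt_dist <- max_nt_dist
  params$collapse <- TRUE
  .buildCloneSet(rec, st$lab, st$v, st$j, params)
}

#' Per-sample clone presence (long form)
#'
#' Copy tallies of each clone per (mouse, strain, subset, replicate) sample,
#' the presence map used by the metrics and overlap modules.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @return Long \code{data.frame(clone_id, mouse_id, strain, subset,
#'   replicate, copies)}.
#' @export
clonePresence <- function(clone_set) {
  rec <- cloneRecords(clone_set)
  agg <- stats::aggregate(
    copies ~ clone_id + mouse_id + strain + subset + replicate,
    data = rec, FUN = sum)
  agg <- agg[order(agg$clone_id, agg$subset, agg$replicate), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Clone table for export
#'
#' One row per clone with per-sample copy columns
#' (\code{mouse.subset.rep<k>}), suitable for TSV export.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @return \code{data.frame}.
#' @export
cloneTable <- function(clone_set) {
  cl <- clones(clone_set)
  pres <- clonePresence(clone_set)
  pres$sample <- paste(pres$mouse_id, pres$subset,
                       paste0("rep", pres$replicate), sep = ".")
  wide <- stats::reshape(
    pres[, c("clone_id", "sample", "copies")],
    idvar = "clone_id", timevar = "sample", direction = "wide")
  names(wide) <- sub("^copies\\.", "", names(wide))
  wide[is.na(wide)] <- 0L
  out <- merge(cl, wide, by = "clone_id", all.x = TRUE, sort = FALSE)
  out <- out[order(out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write clone and assignment tables
#'
#' Writes the clone table (one row per clone with per-sample copies) and the
#' record-to-clone assignment table as TSV.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param clone_path,assignment_path Output TSV paths.
#' @return Invisible character vector of the two paths.
#' @export
writeCloneTables <- function(clone_set, clone_path, assignment_path) {
  utils::write.table(cloneTable(clone_set), clone_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rec <- cloneRecords(clone_set)
  utils::write.table(rec[, c("record_id", "clone_id")], assignment_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(clone_path, assignment_path))
}
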