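# Cross-subset clonal overlap within a mouse: Jaccard on clone presence,
# clone-size-weighted cosine similarity, Venn region counts and presence
# tracks. Clones from different animals arise from independent VDJ events,
# so overlap is never computed across mice; cross-mouse summaries average
# per-mouse matrices.

#' Clone-by-subset presence matrix for one mouse
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param mouse_id Animal to restrict to.
#' @param subsets Column order; defaults to the subsets observed for the
#'   mouse, in \code{\link{ighSubsets}} order.
#' @param merge_replicates Pool the two replicate libraries of each sample
#'   (default TRUE).
#' @return Integer matrix of copy counts, clones (rows, named by clone_id) x
#'   subsets (columns).
#' @export
presenceMatrix <- function(clone_set, mouse_id,
                           subsets = NULL, merge_replicates = TRUE) {
  pres <- clonePresence(clone_set)
  pres <- pres[pres$mouse_id == mouse_id, , drop = FALSE]
  if (!nrow(pres)) stop("no clones for mouse ", mouse_id)
  if (!merge_replicates) pres <- pres[pres$replicate == 1L, , drop = FALSE]
  if (is.null(subsets)) {
    seen <- unique(pres$subset)
    subsets <- c(intersect(ighSubsets(), seen), setdiff(seen, ighSubsets()))
  }
  pres <- pres[pres$subset %in% subsets, , drop = FALSE]
  ids <- sort(unique(pres$clone_id))
  m <- matrix(0L, length(ids), length(subsets),
              dimnames = list(ids, subsets))
  idx <- cbind(match(pres$clone_id, ids), match(pres$subset, subsets))
  for (r in seq_len(nrow(pres)))
    m[idx[r, 1L], idx[r, 2L]] <- m[idx[r, 1L], idx[r, 2L]] + pres$copies[r]
  m
}

#' Pairwise Jaccard similarity between subsets
#'
#' Entry (i, j) is the fraction of clones shared between subsets i and j:
#' \code{|both| / |either|}, each clone counted once per subset.
#'
#' @param presence Clones x subsets matrix (counts or logical); a clone is
#'   present where the entry is > 0.
#' @return Symmetric matrix in [0, 1]. Pairs involving a subset with zero
#'   clones are 0, with a warning.
#' @export
jaccardMatrix <- function(presence) {
  p <- presence > 0
  k <- ncol(p)
  if (k < 2L) stop("need >= 2 subsets")
  if (any(colSums(p) == 0))
    warning("subset(s) with zero clones: ",
            paste(colnames(p)[colSums(p) == 0], collapse = ", "),
            "; their Jaccard entries are 0")
  inter <- crossprod(p)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  m <- ifelse(uni > 0, inter / uni, 0)
  diag(m)[sizes > 0] <- 1
  dimnames(m) <- list(colnames(presence), colnames(presence))
  m
}

#' Pairwise cosine similarity between subset abundance vectors
#'
#' Entry (i, j) is the cosine of the angle between the clone copy-count
#' vectors of subsets i and j over the union clone axis, so clone size is
#' taken into account; in [0, 1] for nonnegative counts.
#'
#' @param abundance Clones x subsets copy-count matrix (nonnegative).
#' @return Symmetric matrix in [0, 1]. Zero-norm subsets give 0 entries with
#'   a warning.
#' @export
cosineMatrix <- function(abundance) {
  a <- as.matrix(abundance)
  if (any(a < 0)) stop("abundance must be nonnegative")
  if (ncol(a) < 2L) stop("need >= 2 subsets")
  nrm <- sqrt(colSums(a^2))
  if (any(nrm == 0))
    warning("subset(s) with zero abundance: ",
            paste(colnames(a)[nrm == 0], collapse = ", "),
            "; their cosine entries are 0")
  dot <- crossprod(a)
  denom <- outer(nrm, nrm)
  m <- ifelse(denom > 0, dot / denom, 0)
  m <- pmin(pmax(m, 0), 1)
  diag(m)[nrm > 0] <- 1
  dimnames(m) <- list(colnames(abundance), colnames(abundance))
  m
}

#' Venn region clone counts
#'
#' Exact count of clones in every subset-membership combination; the regions
#' partition the clones present in at least one subset.
#'
#' @param presence Clones x subsets matrix; presence where entry > 0.
#' @param subsets Subset columns to use (2 to 6); default all columns.
#' @return Named integer vector; names join member subsets with \code{&}.
#' @examples
#' p <- matrix(c(1, 1, 0, 0, 1, 1), ncol = 2,
#'             dimnames = list(1:3, c("A", "B")))
#' vennCounts(p)
#' @export
vennCounts <- function(presence, subsets = colnames(presence)) {
  if (length(subsets) < 2L || length(subsets) > 6L)
    stop("vennCounts supports 2 to 6 subsets")
  p <- presence[, subsets, drop = FALSE] > 0
  member <- apply(p, 1L, function(row)
    paste(subsets[row], collapse = "&"))
  member <- member[member != ""]
  counts <- table(member)
  out <- stats::setNames(as.integer(counts), names(counts))
  # stable region order: by region size then label
  out[order(lengths(strsplit(names(out), "&", fixed = TRUE)), names(out))]
}

#' Presence tracks of clones shared across subsets
#'
#' Rows are clones present in at least \code{min_subsets} subsets, ordered by
#' (number of subsets, descending; total copies, descending); columns are the
#' subsets. Per-subset clone counts (over the displayed rows) are attached.
#'
#' @param presence Clones x subsets copy-count matrix.
#' @param min_subsets Minimum number of subsets a clone must appear in
#'   (default 2).
#' @return List with \code{tracks} (the ordered submatrix) and
#'   \code{subset_clone_counts} (clones per subset among displayed rows).
#' @export
presenceTracks <- function(presence, min_subsets = 2L) {
  nsub <- rowSums(presence > 0)
  keep <- which(nsub >= min_subsets)
  total <- rowSums(presence)
  ord <- keep[order(-nsub[keep], -total[keep])]
  tracks <- presence[ord, , drop = FALSE]
  list(tracks = tracks,
       subset_clone_counts = colSums(tracks > 0))
}

#' Cross-subset clonal overlap for one mouse
#'
#' Builds the clone-by-subset presence matrix of a mouse (replicates merged)
#' and derives the Jaccard matrix, the clone-size-weighted cosine matrix and
#' the Venn region counts.
#'
#' @param clone_set A \linkS4class{CloneSet}.
#' @param mouse_id Animal identifier.
#' @param subsets Optional subset order (default: observed subsets).
#' @return An \linkS4class{OverlapResult}.
#' @export
subsetOverlap <- function(clone_set, mouse_id, subsets = NULL) {
  m <- presenceMatrix(clone_set, mouse_id, subsets = subsets)
  methods::new("OverlapResult",
               mouse_id = as.character(mouse_id),
               subsets = colnames(m),
               jaccard = jaccardMatrix(m),
               cosine = cosineMatrix(m),
               venn = vennCounts(m),
               presence = m)
}

#' Average overlap matrices across mice
#'
#' Clones are not comparable across animals, so cross-mouse aggregation
#' averages the per-mouse similarity matrices entrywise (never pools clones).
#' Only mice sharing the same subset panel are averaged.
#'
#' @param results List of \linkS4class{OverlapResult} objects.
#' @param what \code{"jaccard"} or \code{"cosine"}.
#' @return Averaged symmetric matrix.
#' @export
aggregateOverlap <- function(results, what = c("jaccard", "cosine")) {
  what <- match.arg(what)
  stopifnot(length(results) >= 1L)
  mats <- lapply(results, function(r)
    if (what == "jaccard") jaccard(r) else cosine(r))
  subs <- lapply(mats, colnames)
  if (length(unique(vapply(subs, paste, character(1), collapse = ","))) != 1L)
    stop("all results must share the same subset panel")
  Reduce(`+`, mats) / length(mats)
}
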