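# S4 containers for the clonal-landscape pipeline.
#' @include AllGenerics.R
NULL

#' Sorted B-cell subsets recognised by the pipeline
#'
#' Canonical subset labels, in the fixed display/processing order used
#' throughout the package: follicular B cells (FoB), age-associated B cells
#' (ABC), CD11c+ and CD11c- germinal-center B cells, and CD11c+ and CD11c-
#' plasmablasts/plasma cells.
#'
#' @return Character vector of the six subset labels.
#' @examples
#' ighSubsets()
#' @export
ighSubsets <- function() {
  c("FoB", "ABC", "GCB_CD11cpos", "GCB_CD11cneg", "PB_CD11cpos", "PB_CD11cneg")
}

#' GermlineSet: germline V and J gene segments
#'
#' Holds the germline V and J nucleotide segments used for somatic
#' hypermutation (SHM) counting. Gene labels are stored at the gene level
#' (allele suffixes after \code{*} are stripped; the first allele seen wins).
#'
#' @slot v A \linkS4class{DNAStringSet} of V segments, named by gene label.
#' @slot j A \linkS4class{DNAStringSet} of J segments, named by gene label.
#'
#' @export
setClass("GermlineSet", representation(v = "DNAStringSet", j = "DNAStringSet"))

setValidity("GermlineSet", function(object) {
  msg <- character()
  for (slotname in c("v", "j")) {
    s <- slot(object, slotname)
    if (length(s) == 0L) next
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
      msg <- c(msg, sprintf("all %s segments must be named", slotname))
    else if (anyDuplicated(names(s)))
      msg <- c(msg, sprintf("%s segment labels must be unique", slotname))
    if (any(Biostrings::width(s) == 0L))
      msg <- c(msg, sprintf("%s segments must be nonempty", slotname))
    freq <- Biostrings::alphabetFrequency(s)
    bad <- rowSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
    if (any(bad > 0))
      msg <- c(msg, sprintf("%s segments must use alphabet ACGTN", slotname))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GermlineSet
#'
#' @param v Named character vector or \code{DNAStringSet} of germline V
#'   segments. Names may carry allele suffixes (\code{IGHV1-72*01}); they are
#'   collapsed to gene level.
#' @param j Named character vector or \code{DNAStringSet} of germline J
#'   segments.
#' @return A \linkS4class{GermlineSet}.
#' @examples
#' gl <- GermlineSet(v = c("IGHV1-72*01" = "ACGTACGT"),
#'                   j = c("IGHJ2" = "TGGTTT"))
#' vSegments(gl)
#' @export
GermlineSet <- function(v = character(), j = character()) {
  as_set <- function(x) {
    if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
    if (length(x)) {
      names(x) <- geneLevel(names(x))
      x <- x[!duplicated(names(x))]
    }
    x
  }
  methods::new("GermlineSet", v = as_set(v), j = as_set(j))
}

#' @describeIn GermlineSet-class V segments as a named DNAStringSet
#' @param x A \code{GermlineSet}.
#' @export
setMethod("vSegments", "GermlineSet", function(x) x@v)

#' @describeIn GermlineSet-class J segments as a named DNAStringSet
#' @export
setMethod("jSegments", "GermlineSet", function(x) x@j)

setMethod("show", "GermlineSet", function(object) {
  cat(sprintf("GermlineSet: %d V segments, %d J segments\n",
              length(object@v), length(object@j)))
})

#' CloneSet: inferred B-cell clones and their member rearrangements
#'
#' The result of \code{\link{callClones}}. Clones are inferred per mouse by
#' partitioning rearrangements on (V gene, J gene, CDR3 nucleotide length),
#' single-linkage clustering at >= 85\% CDR3 amino-acid identity, and merging
#' clones whose consensus CDR3 nucleotide sequences are within 2 nt
#' (Hamming), which absorbs erroneous gene calls.
#'
#' @slot clones \code{data.frame} with one row per clone: \code{clone_id},
#'   \code{mouse_id}, \code{strain}, \code{v_call}, \code{j_call},
#'   \code{cdr3_len_nt}, \code{consensus_cdr3_nt}, \code{consensus_cdr3_aa},
#'   \code{n_members}, \code{total_copies}.
#' @slot records the input rearrangement table with a \code{clone_id} column
#'   appended; every record belongs to exactly one clone.
#' @slot params list of the clustering parameters that produced the set
#'   (identity threshold, collapse distance, linkage).
#'
#' @export
setClass("CloneSet",
         representation(clones = "data.frame", records = "data.frame",
                        params = "list"))

setValidity("CloneSet", function(object) {
  cl <- object@clones
  rec <- object@records
  msg <- character()
  if (anyDuplicated(cl$clone_id))
    msg <- c(msg, "clone_id values must be unique")
  if (nrow(rec)) {
    if (!all(rec$clone_id %in% cl$clone_id))
      msg <- c(msg, "every record must belong to a clone in the set")
    tot <- tapply(rec$copies, rec$clone_id, sum)
    idx <- match(cl$clone_id, names(tot))
    if (any(is.na(idx)) || !isTRUE(all(cl$total_copies == as.vector(tot[idx]))))
      msg <- c(msg, "total_copies must equal the sum of member copies")
    len_ok <- nchar(rec$cdr3_nt) ==
      cl$cdr3_len_nt[match(rec$clone_id, cl$clone_id)]
    if (!all(len_ok))
      msg <- c(msg, "all clone members must share the clone's CDR3 length")
  }
  if (nrow(cl) && !all(nchar(cl$consensus_cdr3_nt) == cl$cdr3_len_nt))
    msg <- c(msg, "consensus CDR3 length must equal cdr3_len_nt")
  if (length(msg)) msg else TRUE
})

#' @describeIn CloneSet-class one-row-per-clone summary table
#' @param x A \code{CloneSet}.
#' @param ... Unused.
#' @export
setMethod("clones", "CloneSet", function(x, ...) x@clones)

#' @describeIn CloneSet-class member rearrangements with clone assignments
#' @export
setMethod("cloneRecords", "CloneSet", function(x, ...) x@records)

#' @describeIn CloneSet-class clustering parameters used to build the set
#' @export
setMethod("cloneParams", "CloneSet", function(x) x@params)

#' @describeIn CloneSet-class number of clones
#' @export
setMethod("nClones", "CloneSet", function(x) nrow(x@clones))

setMethod("show", "CloneSet", function(object) {
  cl <- object@clones
  cat(sprintf("CloneSet: %d clones from %d records (%d mice)\n",
              nrow(cl), nrow(object@records),
              length(unique(cl$mouse_id))))
  p <- object@params
  cat(sprintf("  identity threshold %.2f, collapse distance %s nt, %s linkage\n",
              p$threshold,
              if (isTRUE(p$collapse)) p$max_nt_dist else "off (no collapse)",
              p$linkage))
  if (nrow(cl)) {
    top <- utils::head(cl[order(-cl$total_copies), ], 3L)
    cat("  largest clones:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    #%d %s/%s %s (%d copies)\n", top$clone_id[i],
                  top$v_call[i], top$j_call[i], top$consensus_cdr3_aa[i],
                  top$total_copies[i]))
  }
})

#' OverlapResult: cross-subset clonal overlap within one mouse
#'
#' Pairwise clonal sharing between sorted subsets of a single animal:
#' Jaccard similarity on clone presence, clone-size-weighted cosine
#' similarity, exact Venn region counts, and the clone-by-subset presence
#' matrix they were computed from. Clones from different animals arise from
#' independent VDJ events and are never pooled.
#'
#' @slot mouse_id animal identifier.
#' @slot subsets ordered subset labels (matrix row/column order).
#' @slot jaccard symmetric matrix of Jaccard indices in [0, 1].
#' @slot cosine symmetric matrix of cosine similarities in [0, 1].
#' @slot venn named integer vector of clone counts per membership region
#'   (names like \code{"ABC&PB_CD11cpos"}).
#' @slot presence clones x subsets copy-count matrix.
#'
#' @export
setClass("OverlapResult",
         representation(mouse_id = "character", subsets = "character",
                        jaccard = "matrix", cosine = "matrix",
                        venn = "integer", presence = "matrix"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  for (nm in c("jaccard", "cosine")) {
    m <- slot(object, nm)
    if (!isSymmetric(unname(m)))
      msg <- c(msg, sprintf("%s matrix must be symmetric", nm))
    if (any(m < -1e-12 | m > 1 + 1e-12))
      msg <- c(msg, sprintf("%s entries must lie in [0, 1]", nm))
  }
  n_present <- sum(rowSums(object@presence > 0) > 0)
  if (length(object@venn) && sum(object@venn) != n_present)
    msg <- c(msg, "venn region counts must sum to clones present in >=1 subset")
  if (length(msg)) msg else TRUE
})

#' @describeIn OverlapResult-class Jaccard similarity matrix
#' @param x An \code{OverlapResult}.
#' @export
setMethod("jaccard", "OverlapResult", function(x) x@jaccard)

#' @describeIn OverlapResult-class cosine similarity matrix
#' @export
setMethod("cosine", "OverlapResult", function(x) x@cosine)

#' @describeIn OverlapResult-class Venn region clone counts
#' @export
setMethod("vennRegions", "OverlapResult", function(x) x@venn)

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult for mouse %s: %d subsets, %d clones present\n",
              object@mouse_id, length(object@subsets),
              sum(rowSums(object@presence > 0) > 0)))
  od <- object@jaccard[upper.tri(object@jaccard)]
  if (length(od))
    cat(sprintf("  off-diagonal Jaccard: min %.3f, median %.3f, max %.3f\n",
                min(od), stats::median(od), max(od)))
})

#' SimTruth: ground truth emitted by the repertoire simulator
#'
#' Maps every simulated rearrangement to the clone that generated it and
#' records the generative founders, so clone-calling accuracy can be scored
#' (\code{\link{evaluateRecovery}}).
#'
#' @slot records \code{data.frame(record_id, true_clone_id)}.
#' @slot clones \code{data.frame} of founder clones: \code{clone_id},
#'   \code{mouse_id}, \code{v_call}, \code{j_call}, \code{cdr3_nt},
#'   \code{subsets} (comma-separated true memberships).
#' @slot sizes \code{data.frame(clone_id, subset, copies)} of realized
#'   per-subset clone sizes.
#' @slot config the \code{\link{simConfig}} list that generated the data.
#'
#' @export
setClass("SimTruth",
         representation(records = "data.frame", clones = "data.frame",
                        sizes = "data.frame", config = "list"))

setValidity("SimTruth", function(object) {
  msg <- character()
  if (anyDuplicated(object@records$record_id))
    msg <- c(msg, "each record must carry exactly one truth label")
  if (!all(object@records$true_clone_id %in% object@clones$clone_id))
    msg <- c(msg, "every truth label must reference a founder clone")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimTruth-class named vector record_id -> true clone id
#' @param x A \code{SimTruth}.
#' @export
setMethod("truthLabels", "SimTruth", function(x) {
  stats::setNames(x@records$true_clone_id, x@records$record_id)
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d records from %d founder clones (%d mice)\n",
              nrow(object@records), nrow(object@clones),
              length(unique(object@clones$mouse_id))))
})
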