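# AIRR Rearrangement TSV and germline FASTA ingest / export.
#
# The internal canonical representation is one data.frame row per annotated
# rearrangement with gene-level V/J calls and the CDR3 (junction minus the two
# conserved anchor codons) as the clone-defining segment.

.RECORD_COLS <- c("record_id", "mouse_id", "strain", "subset", "replicate",
                  "v_call", "j_call", "cdr3_nt", "cdr3_aa", "copies",
                  "v_observed_nt", "v_mutation_count", "functional")

#' Read annotated IgH rearrangements from an AIRR Rearrangement TSV
#'
#' Ingests an AIRR Rearrangement table (one row per annotated rearrangement)
#' into the package's canonical record table. V/J calls are collapsed to gene
#' level (allele suffix stripped, first gene of an ambiguous call kept). When
#' the file carries a \code{junction} but no \code{cdr3} column, the CDR3 is
#' derived by trimming the two flanking anchor codons (conserved Cys/Trp) from
#' the junction. Rows missing a mandatory field are skipped and reported.
#'
#' @param path Path to a tab-separated AIRR Rearrangement file.
#' @param column_map Optional named character vector mapping AIRR column names
#'   to the names used in the file, e.g. \code{c(duplicate_count = "copies")},
#'   for legacy exports.
#' @return A \code{data.frame} of records (order-preserving, one row per kept
#'   input row) with columns \code{record_id, mouse_id, strain, subset,
#'   replicate, v_call, j_call, cdr3_nt, cdr3_aa, copies, v_observed_nt,
#'   v_mutation_count, functional}. Skipped rows are reported in the
#'   \code{"skip_report"} attribute (see \code{\link{skipReport}}).
#' @seealso \code{\link{writeAirrTsv}}, \code{\link{filterFunctional}}
#' @export
readAirrTsv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      have <- column_map[[std]]
      if (have %in% names(raw)) names(raw)[names(raw) == have] <- std
    }
  }
  mandatory <- c("v_call", "j_call", "duplicate_count",
                 "mouse_id", "strain", "subset", "replicate")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing: ", paste(missing_cols, collapse = ", "))
  if (!any(c("cdr3", "junction") %in% names(raw)))
    stop("mandatory column(s) missing: cdr3 (or junction)")

  n <- nrow(raw)
  get_col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else
    rep(NA_character_, n)

  record_id <- get_col("sequence_id")
  if (all(is.na(record_id))) record_id <- sprintf("row%06d", seq_len(n))

  copies <- suppressWarnings(as.integer(get_col("duplicate_count")))
  cdr3 <- get_col("cdr3")
  junction <- get_col("junction")
  use_junction <- is.na(cdr3) | cdr3 == ""
  jlen <- nchar(junction)
  derived <- ifelse(!is.na(junction) & jlen >= 9L,
                    substr(junction, 4L, jlen - 3L), NA_character_)
  cdr3[use_junction] <- derived[use_junction]

  skip_reason <- rep(NA_character_, n)
  flag <- function(cond, reason)
    skip_reason[is.na(skip_reason) & cond] <<- reason
  flag(is.na(copies) | copies < 1L, "missing or unparseable duplicate_count")
  flag(is.na(cdr3) | cdr3 == "", "missing cdr3/junction")
  flag(get_col("v_call") == "" | is.na(get_col("v_call")), "missing v_call")
  flag(get_col("j_call") == "" | is.na(get_col("j_call")), "missing j_call")
  for (nm in c("mouse_id", "strain", "subset", "replicate"))
    flag(get_col(nm) == "" | is.na(get_col(nm)),
         paste("missing", nm))

  keep <- is.na(skip_reason)
  cdr3_aa <- get_col("cdr3_aa")
  need_aa <- keep & (is.na(cdr3_aa) | cdr3_aa == "")
  translatable <- need_aa & nchar(cdr3) %% 3L == 0L
  if (any(translatable))
    cdr3_aa[translatable] <- translateCdr3(cdr3[translatable])
  cdr3_aa[need_aa & !translatable] <- NA_character_

  productive <- get_col("productive")
  func <- rep(NA, n)
  has_flag <- !is.na(productive) & productive != ""
  func[has_flag] <- toupper(productive[has_flag]) %in% c("T", "TRUE", "1")
  derive <- keep & !has_flag
  func[derive] <- nchar(cdr3[derive]) %% 3L == 0L &
    !grepl("*", cdr3_aa[derive], fixed = TRUE) & !is.na(cdr3_aa[derive])

  v_obs <- get_col("v_sequence_alignment")
  v_obs[!is.na(v_obs) & v_obs == ""] <- NA_character_
  v_mut <- suppressWarnings(as.integer(get_col("v_mutation_count")))

  out <- data.frame(
    record_id = record_id,
    mouse_id = get_col("mouse_id"),
    strain = get_col("strain"),
    subset = get_col("subset"),
    replicate = suppressWarnings(as.integer(get_col("replicate"))),
    v_call = geneLevel(get_col("v_call")),
    j_call = geneLevel(get_col("j_call")),
    cdr3_nt = cdr3,
    cdr3_aa = cdr3_aa,
    copies = copies,
    v_observed_nt = v_obs,
    v_mutation_count = v_mut,
    functional = func,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL

  skipped <- data.frame(row = which(!keep),
                        record_id = record_id[!keep],
                        reason = skip_reason[!keep],
                        stringsAsFactors = FALSE)
  attr(out, "skip_report") <- skipped
  out
}

#' Skip report from an ingest
#'
#' @param records A record table returned by \code{\link{readAirrTsv}}.
#' @return \code{data.frame(row, record_id, reason)} of skipped input rows
#'   (zero rows when nothing was skipped).
#' @export
skipReport <- function(records) {
  attr(records, "skip_report") %||%
    data.frame(row = integer(), record_id = character(),
               reason = character(), stringsAsFactors = FALSE)
}

#' Write records as an AIRR Rearrangement TSV
#'
#' Inverse of \code{\link{readAirrTsv}} on the canonical representation: a
#' read-write-read round trip reproduces every field.
#'
#' @param records Canonical record \code{data.frame}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeAirrTsv <- function(records, path) {
  validateRecords(records)
  out <- data.frame(
    sequence_id = records$record_id,
    mouse_id = records$mouse_id,
    strain = records$strain,
    subset = records$subset,
    replicate = records$replicate,
    v_call = records$v_call,
    j_call = records$j_call,
    cdr3 = records$cdr3_nt,
    cdr3_aa = records$cdr3_aa,
    duplicate_count = records$copies,
    productive = ifelse(is.na(records$functional), "",
                        ifelse(records$functional, "T", "F")),
    v_sequence_alignment = records$v_observed_nt,
    v_mutation_count = records$v_mutation_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# Checks the canonical record table; stops with the offending column.
validateRecords <- function(records) {
  missing_cols <- setdiff(setdiff(.RECORD_COLS,
                                  c("v_observed_nt", "v_mutation_count",
                                    "cdr3_aa")),
                          names(records))
  if (length(missing_cols))
    stop("record table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records)) {
    if (any(is.na(records$copies)) || any(records$copies < 1L))
      stop("copies must be integers >= 1")
    if (any(is.na(records$replicate)) || any(records$replicate < 1L))
      stop("replicate must be integers >= 1")
    if (any(is.na(records$cdr3_nt) | records$cdr3_nt == ""))
      stop("cdr3_nt must be nonempty")
    aa <- records$cdr3_aa
    has_aa <- !is.na(aa)
    if (any(has_aa) &&
        !all(nchar(records$cdr3_nt[has_aa]) == 3L * nchar(aa[has_aa])))
      stop("cdr3_nt length must be 3x cdr3_aa length where cdr3_aa is present")
  }
  invisible(records)
}

#' Translate CDR3 nucleotide sequences
#'
#' Standard-code translation of in-frame CDR3 nucleotide sequences. Codons
#' containing \code{N} translate to \code{X}; stop codons to \code{*}.
#'
#' @param cdr3_nt Character vector of nucleotide sequences (alphabet ACGTN),
#'   each with length divisible by 3.
#' @return Character vector of amino-acid sequences.
#' @examples
#' translateCdr3(c("TGTGCTAGA", "TGA", "TGN"))
#' @export
translateCdr3 <- function(cdr3_nt) {
  if (any(is.na(cdr3_nt))) stop("cdr3_nt must not contain NA")
  if (any(nchar(cdr3_nt) %% 3L != 0L))
    stop("cdr3_nt length must be divisible by 3")
  if (any(grepl("[^ACGTN]", cdr3_nt)))
    stop("cdr3_nt alphabet must be ACGTN")
  code <- Biostrings::GENETIC_CODE
  u <- unique(cdr3_nt)
  tr <- vapply(u, function(s) {
    if (nchar(s) == 0L) return("")
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  tr[match(cdr3_nt, u)]
}

#' Keep functional (productive) rearrangements
#'
#' Retains records flagged functional. Where the flag is absent (NA) it is
#' computed as: CDR3 length divisible by 3 and no stop codon in the
#' translation. Idempotent.
#'
#' @param records Canonical record \code{data.frame}.
#' @return The functional subset, with the \code{functional} flag filled in.
#' @export
filterFunctional <- function(records) {
  if (!nrow(records)) return(records)
  func <- records$functional
  na <- is.na(func)
  if (any(na)) {
    inframe <- nchar(records$cdr3_nt[na]) %% 3L == 0L
    aa <- rep(NA_character_, sum(na))
    aa[inframe] <- translateCdr3(records$cdr3_nt[na][inframe])
    func[na] <- inframe & !grepl("*", aa, fixed = TRUE)
  }
  records$functional <- func
  out <- records[func, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skip_report") <- attr(records, "skip_report")
  out
}

#' Read germline V and J segments from FASTA
#'
#' @param v_path,j_path FASTA files of germline V and J nucleotide segments.
#' @return A \linkS4class{GermlineSet}.
#' @export
readGermlineFasta <- function(v_path, j_path) {
  GermlineSet(v = Biostrings::readDNAStringSet(v_path),
              j = Biostrings::readDNAStringSet(j_path))
}

#' Write germline V and J segments to FASTA
#'
#' @param germlines A \linkS4class{GermlineSet}.
#' @param v_path,j_path Output FASTA paths.
#' @return Invisible character vector of the two paths.
#' @export
writeGermlineFasta <- function(germlines, v_path, j_path) {
  Biostrings::writeXStringSet(vSegments(germlines), v_path)
  Biostrings::writeXStringSet(jSegments(germlines), j_path)
  invisible(c(v_path, j_path))
}
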