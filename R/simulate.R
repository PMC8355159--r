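# Synthetic IgH repertoire generator with ground-truth clone labels.
#
# Emulates the study design the pipeline targets: 4 mouse strains x 6 sorted
# B-cell subsets x 2 replicate libraries per sample, with subset-specific
# clone-size skew (FoB flattest, PB/PC steepest), an SHM gradient
# (FoB < ABC < GCB ~ PB), tunable cross-subset clone sharing with an elevated
# ABC-PB/PC term, and occasional erroneous V gene calls within a clone.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulator configuration
#'
#' Builds and validates the parameter set for
#' \code{\link{simulateRepertoire}}. Defaults emulate the study design: four
#' strains with two mice each, six sorted subsets per mouse with 200 clones
#' each, duplicate sequencing libraries, a clone-size skew gradient
#' (\code{alpha}, Zipf rank exponent: FoB flattest, PB/PC steepest), an SHM
#' rate gradient (expected mutations per V nucleotide: FoB < ABC < GCB = PB),
#' baseline pairwise clone sharing of 0.05 with the ABC-PB/PC pairs elevated
#' to 0.25, a 1\% per-base CDR3 substitution rate for within-clone variants,
#' and a 2\% V gene miscall rate.
#'
#' @param seed Integer seed fixing the output bit-exactly.
#' @param strains Character vector of strain labels.
#' @param n_mice_per_strain Mice simulated per strain.
#' @param subsets Sorted-subset labels (default \code{\link{ighSubsets}}).
#' @param n_clones Clones per subset sample; scalar or named per subset.
#' @param alpha Zipf clone-size rank exponent per subset (> 0; larger =
#'   steeper skew = higher D20); scalar or named per subset.
#' @param copies_total Sequence copies per subset sample (>= n_clones).
#' @param sharing Baseline pairwise probability that a clone of one subset is
#'   also seeded into another; scalar, or full symmetric matrix
#'   (subsets x subsets).
#' @param sharing_boost Named list of elevated pairwise sharing values, names
#'   like \code{"ABC:PB_CD11cpos"}; ignored when \code{sharing} is a matrix.
#' @param shm_rate Expected mutations per V-segment nucleotide per subset;
#'   scalar or named per subset.
#' @param v_len,j_len Germline V and J segment lengths (nt).
#' @param n_v_genes,n_v_families,n_j_genes Germline panel dimensions; V genes
#'   are grouped into families of similar sequences (miscalls stay within a
#'   family).
#' @param family_divergence Per-base substitution rate separating sister V
#'   genes of one family.
#' @param cdr3_aa_lengths Integer support of the founder CDR3 amino-acid
#'   length distribution.
#' @param cdr3_aa_length_probs Sampling weights over
#'   \code{cdr3_aa_lengths}; default a peaked triangular distribution.
#' @param within_clone_variant_rate Per-base CDR3 substitution rate of
#'   non-founder variants (keep well below 0.05 so expected within-clone
#'   identity stays above the 0.85 clustering threshold).
#' @param extra_variants_lambda Poisson mean of extra sequence variants per
#'   clone per subset (beyond the founder sequence).
#' @param gene_call_error_rate Probability that a variant's V call is
#'   relabeled to a sister gene of the same family.
#' @param replicate_split Binomial fraction of each variant's copies assigned
#'   to replicate library 1.
#' @param emit_v \code{"alignment"} (emit the germline-aligned V segment) or
#'   \code{"count"} (emit the true mutation count instead).
#' @return A validated config list of class \code{"sim_config"}.
#' @export
simConfig <- function(seed = 1L,
                      strains = c("WT", "DKO-F", "DKO-M", "Yaa-DKO-M"),
                      n_mice_per_strain = 2L,
                      subsets = ighSubsets(),
                      n_clones = 200L,
                      alpha = c(FoB = 0.4, ABC = 0.9,
                                GCB_CD11cpos = 1.3, GCB_CD11cneg = 1.3,
                                PB_CD11cpos = 1.9, PB_CD11cneg = 1.9),
                      copies_total = 2000L,
                      sharing = 0.05,
                      sharing_boost = list("ABC:PB_CD11cpos" = 0.25,
                                           "ABC:PB_CD11cneg" = 0.25),
                      shm_rate = c(FoB = 5e-4, ABC = 6e-3,
                                   GCB_CD11cpos = 0.02, GCB_CD11cneg = 0.02,
                                   PB_CD11cpos = 0.02, PB_CD11cneg = 0.02),
                      v_len = 294L, j_len = 48L,
                      n_v_genes = 60L, n_v_families = 15L, n_j_genes = 4L,
                      family_divergence = 0.02,
                      cdr3_aa_lengths = 9:22,
                      cdr3_aa_length_probs = NULL,
                      within_clone_variant_rate = 0.01,
                      extra_variants_lambda = 0.7,
                      gene_call_error_rate = 0.02,
                      replicate_split = 0.5,
                      emit_v = c("alignment", "count")) {
  emit_v <- match.arg(emit_v)
  per_subset <- function(x, what, lower = 0) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(x, length(subsets)), subsets)
    if (!all(subsets %in% names(x)))
      stop(what, " must be a scalar or named for every subset")
    x <- x[subsets]
    if (any(x < lower)) stop(what, " must be >= ", lower)
    x
  }
  n_clones <- per_subset(as.integer(n_clones), "n_clones", lower = 1)
  alpha <- per_subset(alpha, "alpha")
  if (any(alpha <= 0)) stop("alpha must be > 0")
  shm_rate <- per_subset(shm_rate, "shm_rate")
  if (any(shm_rate < 0 | shm_rate > 1)) stop("shm_rate must be in [0, 1]")
  if (is.matrix(sharing)) {
    if (!all(dim(sharing) == length(subsets)) ||
        !isTRUE(all.equal(sharing, t(sharing))))
      stop("sharing matrix must be symmetric subsets x subsets")
    smat <- sharing
    dimnames(smat) <- list(subsets, subsets)
  } else {
    smat <- matrix(sharing, length(subsets), length(subsets),
                   dimnames = list(subsets, subsets))
    for (nm in names(sharing_boost)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      if (!all(pair %in% subsets)) next
      smat[pair[1L], pair[2L]] <- sharing_boost[[nm]]
      smat[pair[2L], pair[1L]] <- sharing_boost[[nm]]
    }
  }
  diag(smat) <- 0
  if (any(smat < 0 | smat > 1)) stop("sharing probabilities must be in [0, 1]")
  for (r in c("within_clone_variant_rate", "gene_call_error_rate",
              "replicate_split", "family_divergence")) {
    val <- get(r)
    if (val < 0 || val > 1) stop(r, " must be in [0, 1]")
  }
  if (any(copies_total < n_clones))
    stop("infeasible config: copies_total must be >= n_clones ",
         "(every clone needs at least one copy)")
  if (n_v_genes %% n_v_families != 0L)
    stop("n_v_genes must be a multiple of n_v_families")
  if (is.null(cdr3_aa_length_probs)) {
    mid <- 13
    cdr3_aa_length_probs <- pmax(1, 8 - abs(cdr3_aa_lengths - mid))
  }
  cdr3_aa_length_probs <- cdr3_aa_length_probs / sum(cdr3_aa_length_probs)
  structure(list(
    seed = as.integer(seed), strains = strains,
    n_mice_per_strain = as.integer(n_mice_per_strain),
    subsets = subsets, n_clones = n_clones, alpha = alpha,
    copies_total = as.integer(copies_total), sharing = smat,
    shm_rate = shm_rate, v_len = as.integer(v_len), j_len = as.integer(j_len),
    n_v_genes = as.integer(n_v_genes), n_v_families = as.integer(n_v_families),
    n_j_genes = as.integer(n_j_genes), family_divergence = family_divergence,
    cdr3_aa_lengths = as.integer(cdr3_aa_lengths),
    cdr3_aa_length_probs = cdr3_aa_length_probs,
    within_clone_variant_rate = within_clone_variant_rate,
    extra_variants_lambda = extra_variants_lambda,
    gene_call_error_rate = gene_call_error_rate,
    replicate_split = replicate_split, emit_v = emit_v
  ), class = "sim_config")
}

# Random in-frame CDR3 nucleotide sequence: conserved Cys first codon, Trp
# last codon, no stop codons in between.
.randomCdr3 <- function(aa_len) {
  codons <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)
  inner <- sample(codons, max(aa_len - 2L, 0L), replace = TRUE)
  paste(c(sample(c("TGT", "TGC"), 1L), inner, "TGG"), collapse = "")
}

# Substitute `n_mut` random positions (or each position with prob `rate`)
# with a different concrete base.
.mutateSeq <- function(seq, n_mut = NULL, rate = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- if (!is.null(n_mut)) {
    if (n_mut == 0L) integer() else
      sample.int(length(ch), min(n_mut, length(ch)))
  } else {
    which(stats::runif(length(ch)) < rate)
  }
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

.makeGermlines <- function(config) {
  per_family <- config$n_v_genes %/% config$n_v_families
  v <- character(config$n_v_genes)
  vnames <- character(config$n_v_genes)
  families <- integer(config$n_v_genes)
  k <- 0L
  for (f in seq_len(config$n_v_families)) {
    founder <- paste(sample(c("A", "C", "G", "T"), config$v_len,
                            replace = TRUE), collapse = "")
    for (g in seq_len(per_family)) {
      k <- k + 1L
      v[k] <- if (g == 1L) founder else
        .mutateSeq(founder, rate = config$family_divergence)
      vnames[k] <- sprintf("IGHV%d-%d", f, g)
      families[k] <- f
    }
  }
  j <- vapply(seq_len(config$n_j_genes), function(i)
    paste(sample(c("A", "C", "G", "T"), config$j_len, replace = TRUE),
          collapse = ""), character(1))
  names(v) <- vnames
  names(j) <- sprintf("IGHJ%d", seq_len(config$n_j_genes))
  list(set = GermlineSet(v = v, j = j),
       v_names = vnames, v_families = families)
}

# Subset memberships for one mouse under the pairwise sharing model. Subsets
# are filled in panel order; a clone already present in earlier subsets
# enters subset k with probability 1 - prod(1 - sharing[j, k]) over the
# earlier subsets j that contain it; the remainder of subset k's n_k slots
# are fresh founder clones. With exactly two subsets and sharing p this makes
# the shared count Binomial(n, p), giving expected Jaccard p / (2 - p).
.drawMemberships <- function(config) {
  subsets <- config$subsets
  member <- list()  # clone index -> character vector of subsets
  n_total <- 0L
  for (k in seq_along(subsets)) {
    sk <- subsets[k]
    n_k <- config$n_clones[[sk]]
    chosen <- integer()
    if (k > 1L && n_total > 0L) {
      p_inc <- vapply(seq_len(n_total), function(ci) {
        in_prev <- member[[ci]]
        1 - prod(1 - config$sharing[in_prev, sk])
      }, numeric(1))
      cand <- which(stats::runif(n_total) < p_inc)
      chosen <- if (length(cand) > n_k) sort(sample(cand, n_k)) else cand
    }
    n_fresh <- n_k - length(chosen)
    fresh <- if (n_fresh > 0L) n_total + seq_len(n_fresh) else integer()
    for (ci in fresh) member[[ci]] <- character()
    n_total <- n_total + n_fresh
    for (ci in c(chosen, fresh)) member[[ci]] <- c(member[[ci]], sk)
  }
  member
}

#' Simulate an annotated IgH repertoire with ground truth
#'
#' Generates founder clones (random V/J and in-frame CDR3), assigns them to
#' subsets under the pairwise sharing model, draws per-subset clone sizes
#' from a Zipf rank law with subset-specific exponent, derives member
#' sequence variants by CDR3 substitution, applies subset-specific Poisson
#' SHM to the V segment, injects V gene miscalls within germline families,
#' and splits copies binomially into two replicate libraries. Deterministic
#' under \code{config$seed}.
#'
#' @param config A \code{\link{simConfig}} list.
#' @return List with \code{records} (canonical record \code{data.frame}),
#'   \code{truth} (a \linkS4class{SimTruth}) and \code{germlines}
#'   (a \linkS4class{GermlineSet}).
#' @examples
#' sim <- simulateRepertoire(simConfig(seed = 7, strains = "WT",
#'                                     n_mice_per_strain = 1,
#'                                     n_clones = 25, copies_total = 250))
#' head(sim$records)
#' @export
simulateRepertoire <- function(config = simConfig()) {
  stopifnot(inherits(config, "sim_config"))
  withSeed(config$seed, .simulateImpl(config))
}

.simulateImpl <- function(config) {
  gl <- .makeGermlines(config)
  vseq <- as.character(vSegments(gl$set))
  rec_blocks <- list()
  clone_rows <- list()
  size_rows <- list()
  clone_counter <- 0L

  mice <- do.call(rbind, lapply(config$strains, function(st)
    data.frame(mouse_id = sprintf("%s_m%d", st,
                                  seq_len(config$n_mice_per_strain)),
               strain = st, stringsAsFactors = FALSE)))

  for (mi in seq_len(nrow(mice))) {
    mouse <- mice$mouse_id[mi]; strain <- mice$strain[mi]
    member <- .drawMemberships(config)
    n_cl <- length(member)
    # founders
    aa_len <- sample(config$cdr3_aa_lengths, n_cl, replace = TRUE,
                     prob = config$cdr3_aa_length_probs)
    founder_nt <- vapply(aa_len, .randomCdr3, character(1))
    founder_v <- sample(gl$v_names, n_cl, replace = TRUE)
    founder_j <- sample(names(jSegments(gl$set)), n_cl, replace = TRUE)
    clone_ids <- clone_counter + seq_len(n_cl)
    clone_counter <- clone_counter + n_cl
    clone_rows[[length(clone_rows) + 1L]] <- data.frame(
      clone_id = clone_ids, mouse_id = mouse,
      v_call = founder_v, j_call = founder_j, cdr3_nt = founder_nt,
      subsets = vapply(member, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)

    for (sk in config$subsets) {
      in_subset <- which(vapply(member, function(m) sk %in% m, logical(1)))
      n_k <- length(in_subset)
      if (!n_k) next
      # Zipf rank sizes: random rank permutation, 1 guaranteed copy each
      ranks <- sample.int(n_k)
      w <- ranks^(-config$alpha[[sk]])
      extra <- config$copies_total - n_k
      sizes <- rep(1L, n_k)
      if (extra > 0L)
        sizes <- sizes + as.integer(stats::rmultinom(1L, extra, prob = w))
      size_rows[[length(size_rows) + 1L]] <- data.frame(
        clone_id = clone_ids[in_subset], subset = sk, copies = sizes,
        stringsAsFactors = FALSE)

      # sequence variants per clone in this subset
      n_var <- pmin(1L + stats::rpois(n_k, config$extra_variants_lambda),
                    sizes)
      clone_of_var <- rep(seq_len(n_k), n_var)     # index into in_subset
      var_index <- sequence(n_var)
      nv <- length(clone_of_var)
      var_sizes <- integer(nv)
      off <- 0L
      for (ci in seq_len(n_k)) {
        vs <- rep(1L, n_var[ci])
        if (sizes[ci] > n_var[ci])
          vs <- vs + as.integer(stats::rmultinom(
            1L, sizes[ci] - n_var[ci], prob = rep(1, n_var[ci])))
        var_sizes[off + seq_len(n_var[ci])] <- vs
        off <- off + n_var[ci]
      }
      cl_abs <- in_subset[clone_of_var]            # index into clone pool
      cdr3 <- founder_nt[cl_abs]
      mutate_me <- which(var_index > 1L)
      for (i in mutate_me)
        cdr3[i] <- .mutateSeq(cdr3[i],
                              rate = config$within_clone_variant_rate)
      n_mut <- stats::rpois(nv, config$shm_rate[[sk]] * config$v_len)
      true_v <- founder_v[cl_abs]
      v_obs <- if (config$emit_v == "alignment") {
        vapply(seq_len(nv), function(i)
          .mutateSeq(vseq[[true_v[i]]], n_mut = n_mut[i]), character(1))
      } else rep(NA_character_, nv)
      call_v <- true_v
      miscall <- which(stats::runif(nv) < config$gene_call_error_rate)
      for (i in miscall) {
        fam <- gl$v_families[match(true_v[i], gl$v_names)]
        sisters <- gl$v_names[gl$v_families == fam & gl$v_names != true_v[i]]
        if (length(sisters)) call_v[i] <- sample(sisters, 1L)
      }
      r1 <- stats::rbinom(nv, var_sizes, config$replicate_split)
      rep_copies <- c(r1, var_sizes - r1)
      rep_lab <- rep(1:2, each = nv)
      keep <- rep_copies > 0L
      ii <- rep(seq_len(nv), 2L)[keep]
      rec_blocks[[length(rec_blocks) + 1L]] <- data.frame(
        record_id = sprintf("%s|%s|c%d|v%d|r%d", mouse, sk,
                            clone_ids[cl_abs][ii], var_index[ii],
                            rep_lab[keep]),
        mouse_id = mouse, strain = strain, subset = sk,
        replicate = rep_lab[keep],
        v_call = call_v[ii], j_call = founder_j[cl_abs][ii],
        cdr3_nt = cdr3[ii], cdr3_aa = NA_character_,
        copies = rep_copies[keep],
        v_observed_nt = v_obs[ii],
        v_mutation_count = if (config$emit_v == "count") n_mut[ii]
                           else NA_integer_,
        functional = TRUE,
        true_clone_id = clone_ids[cl_abs][ii],
        stringsAsFactors = FALSE)
    }
  }

  records <- do.call(rbind, rec_blocks)
  records$cdr3_aa <- translateCdr3(records$cdr3_nt)
  rownames(records) <- NULL
  truth_records <- records[, c("record_id", "true_clone_id")]
  records$true_clone_id <- NULL
  truth <- methods::new(
    "SimTruth", records = truth_records,
    clones = do.call(rbind, clone_rows),
    sizes = do.call(rbind, size_rows),
    config = unclass(config))
  list(records = records, truth = truth, germlines = gl$set)
}

#' Score clone-calling accuracy against simulator ground truth
#'
#' Compares a called \linkS4class{CloneSet} with the generating partition:
#' adjusted Rand index plus merge errors (called clones spanning >= 2 true
#' clones) and split errors (true clones spanning >= 2 called clones).
#'
#' @param called A \linkS4class{CloneSet} built from the simulated records.
#' @param truth The \linkS4class{SimTruth} from the same simulation.
#' @return List with \code{ari}, \code{n_merge}, \code{n_split}.
#' @export
evaluateRecovery <- function(called, truth) {
  rec <- cloneRecords(called)
  lab_true <- truthLabels(truth)
  if (!setequal(rec$record_id, names(lab_true)) ||
      nrow(rec) != length(lab_true))
    stop("called clone set does not cover exactly the simulated records")
  truth_of <- lab_true[rec$record_id]
  called_of <- rec$clone_id
  ari <- mclust::adjustedRandIndex(truth_of, called_of)
  cross <- table(called_of, truth_of)
  list(ari = ari,
       n_merge = sum(rowSums(cross > 0) >= 2L),
       n_split = sum(colSums(cross > 0) >= 2L))
}

#' Write a simulation to disk
#'
#' Emits the AIRR Rearrangement TSV, germline V/J FASTA files, the truth
#' table (record to clone map) as TSV, and the generating configuration
#' (including the seed) as JSON.
#'
#' @param sim Result of \code{\link{simulateRepertoire}}.
#' @param dir Output directory (created if needed).
#' @return Invisible named character vector of the written paths.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "repertoire.airr.tsv"),
             v = file.path(dir, "germline_v.fasta"),
             j = file.path(dir, "germline_j.fasta"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "sim_config.json"))
  writeAirrTsv(sim$records, paths[["records"]])
  writeGermlineFasta(sim$germlines, paths[["v"]], paths[["j"]])
  utils::write.table(sim$truth@records, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$truth@config
  cfg$sharing <- as.data.frame(cfg$sharing)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
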