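test_that("d20Index matches hand-enumerable fixtures", {
  expect_equal(d20Index(rep(3, 15)), 1.0)            # n <= 20: all clones
  expect_equal(d20Index(rep(1, 100)), 0.2)           # uniform
  expect_equal(d20Index(c(50, rep(10, 9), rep(1, 30))), 150 / 170)
  expect_error(d20Index(numeric()), "empty")
})

test_that("d20Index is permutation invariant and rewards copy concentration", {
  set.seed(42)
  for (i in 1:25) {
    x <- sample(1:50, sample(5:60, 1), replace = TRUE)
    expect_equal(d20Index(sample(x)), d20Index(x))
  }
  # moving copy mass from a rank > 20 clone to a top-20 clone cannot lower D20
  x <- c(rep(10, 25), rep(5, 25))
  y <- x; y[1] <- y[1] + 3; y[30] <- y[30] - 3
  expect_gte(d20Index(y), d20Index(x))
})

test_that("replicateJaccard follows set arithmetic with the empty-set rule", {
  expect_equal(replicateJaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(replicateJaccard(1:4, 1:4), 1.0)
  expect_equal(replicateJaccard(1:3, 4:6), 0.0)
  expect_warning(z <- replicateJaccard(character(), character()), "empty")
  expect_equal(z, 0)
  # symmetry and bounds on random sets
  set.seed(7)
  for (i in 1:20) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(1:10, 1))
    expect_equal(replicateJaccard(a, b), replicateJaccard(b, a))
    j <- replicateJaccard(a, b)
    expect_true(j >= 0 && j <= 1)
    expect_equal(j == 1, setequal(a, b))
  }
})

test_that("replicateOverlap scores each sorted sample's two libraries", {
  nt <- c("TGTGCTAGATGG", "GGGCCCAAATTT", "ATGATGATGATG")
  rec <- rbind(
    makeRecords(nt[1:2], record_id = c("a", "b"), replicate = 1),
    makeRecords(nt[2:3], record_id = c("c", "d"), replicate = 2),
    makeRecords(nt[1], record_id = "e", subset = "ABC", replicate = 1))
  ro <- replicateOverlap(callClones(rec))
  fob <- ro[ro$subset == "FoB", ]
  expect_equal(fob$jaccard, 1 / 3)      # {1,2} vs {2,3}
  abc <- ro[ro$subset == "ABC", ]
  expect_equal(abc$jaccard, 0)          # replicate 2 empty
})

test_that("clone mutation percent is the copy-weighted member mean", {
  germ <- GermlineSet(v = c("IGHV1-1" = strrep("A", 100)),
                      j = c("IGHJ1" = "TGGTTT"))
  mut_seq <- function(k) paste0(strrep("C", k), strrep("A", 100 - k))
  nt <- "TGTGCTAGATGG"
  rec <- rbind(
    makeRecords(nt, copies = 3, v_observed_nt = mut_seq(2), record_id = "a"),
    makeRecords(nt, copies = 1, v_observed_nt = mut_seq(5), record_id = "b"))
  cs <- callClones(rec)
  expect_equal(cloneMutationPercent(cs, clones(cs)$clone_id[1], "FoB", germ),
               (2 * 3 + 5 * 1) / 4)
  # germline-identical members are 0%
  rec0 <- makeRecords(nt, v_observed_nt = strrep("A", 100))
  cs0 <- callClones(rec0)
  expect_equal(cloneMutationPercent(cs0, 1, "FoB", germ), 0)
  # 3 mutations over 300 compared positions = 1%
  germ300 <- GermlineSet(v = c("IGHV1-1" = strrep("G", 300)),
                         j = c("IGHJ1" = "TGG"))
  rec1 <- makeRecords(nt, v_observed_nt = paste0(strrep("T", 3),
                                                 strrep("G", 297)))
  expect_equal(cloneMutationPercent(callClones(rec1), 1, "FoB", germ300), 1.0)
  # v_mutation_count path agrees, with the full germline as denominator
  rec2 <- makeRecords(nt, v_mutation_count = 3L)
  expect_equal(cloneMutationPercent(callClones(rec2), 1, "FoB", germ300), 1.0)
  # N positions are excluded from the comparison
  recN <- makeRecords(nt, v_observed_nt = paste0("N", strrep("C", 1),
                                                 strrep("A", 98)))
  expect_equal(cloneMutationPercent(callClones(recN), 1, "FoB", germ),
               100 * 1 / 99)
})

test_that("per-subset SHM is recomputed from each subset's sequences only", {
  germ <- GermlineSet(v = c("IGHV1-1" = strrep("A", 100)),
                      j = c("IGHJ1" = "TGGTTT"))
  mut_seq <- function(k) paste0(strrep("C", k), strrep("A", 100 - k))
  nt <- "TGTGCTAGATGG"
  rec <- rbind(
    makeRecords(nt, subset = "FoB", v_observed_nt = mut_seq(0),
                record_id = "a"),
    makeRecords(nt, subset = "GCB_CD11cpos", v_observed_nt = mut_seq(8),
                record_id = "b"))
  cs <- callClones(rec)
  expect_equal(nClones(cs), 1L)
  shm <- shmByCloneSubset(cs, germ)
  expect_equal(shm$shm_percent[shm$subset == "FoB"], 0)
  expect_equal(shm$shm_percent[shm$subset == "GCB_CD11cpos"], 8)
})

test_that("shmFraction enumerates mutated clones under both weightings", {
  germ <- GermlineSet(v = c("IGHV1-1" = strrep("A", 200)),
                      j = c("IGHJ1" = "TGGTTT"))
  mut_seq <- function(pct) paste0(strrep("C", round(pct * 2)),
                                  strrep("A", 200 - round(pct * 2)))
  # four clones: mutation % {0, 0.5, 2, 3}, subset copies {10, 10, 1, 1}
  nts <- c("TGTGCTAGATGG", "GGGCCCAAATTT", "ATGATGATGATG", "CACGTGCACGTG")
  rec <- do.call(rbind, lapply(1:4, function(i)
    makeRecords(nts[i], copies = c(10, 10, 1, 1)[i],
                v_observed_nt = mut_seq(c(0, 0.5, 2, 3)[i]),
                record_id = paste0("r", i))))
  cs <- callClones(rec)
  expect_equal(nClones(cs), 4L)
  expect_equal(shmFraction(cs, germ, "FoB", mutated_threshold_percent = 1),
               2 / 4)
  expect_equal(shmFraction(cs, germ, "FoB", mutated_threshold_percent = 1,
                           weighted = TRUE), 2 / 22)
  # strict threshold: every clone with any mutation counts
  expect_equal(shmFraction(cs, germ, "FoB",
                           mutated_threshold_percent = 1e-9), 3 / 4)
  # all-unmutated stratum is 0 in both modes
  rec0 <- makeRecords(nts[1], v_observed_nt = strrep("A", 200))
  cs0 <- callClones(rec0)
  expect_equal(shmFraction(cs0, germ, "FoB"), 0)
  expect_equal(shmFraction(cs0, germ, "FoB", weighted = TRUE), 0)
  expect_error(shmFraction(cs, germ, "ABC"), "no clones")
  # weighted and unweighted coincide under equal subset copy counts
  rec_eq <- do.call(rbind, lapply(1:4, function(i)
    makeRecords(nts[i], copies = 5,
                v_observed_nt = mut_seq(c(0, 0.5, 2, 3)[i]),
                record_id = paste0("e", i))))
  cs_eq <- callClones(rec_eq)
  expect_equal(shmFraction(cs_eq, germ, "FoB"),
               shmFraction(cs_eq, germ, "FoB", weighted = TRUE))
})

test_that("CDR3 lengths are counted once per clone per stratum", {
  nt30 <- strrep("GCT", 10)            # 30 nt
  rec <- rbind(
    makeRecords(nt30, subset = "FoB", record_id = "a"),
    makeRecords(nt30, subset = "ABC", record_id = "b"),
    makeRecords(nt30, subset = "ABC", replicate = 2, record_id = "c"))
  cs <- callClones(rec)
  expect_equal(nClones(cs), 1L)
  len <- cdr3LengthDistribution(cs)
  # one entry per (strain, subset), replicates never double count
  expect_equal(nrow(len), 2L)
  expect_setequal(len$subset, c("FoB", "ABC"))
  expect_true(all(len$cdr3_len_nt == 30L))
  # three singleton clones -> multiset {12, 33, 45}, median 33
  rec2 <- rbind(
    makeRecords(strrep("GCT", 4), record_id = "x"),
    makeRecords(strrep("GCA", 11), record_id = "y"),
    makeRecords(strrep("GGT", 15), record_id = "z"))
  len2 <- cdr3LengthDistribution(callClones(rec2))
  expect_setequal(len2$cdr3_len_nt, c(12L, 33L, 45L))
  expect_equal(median(len2$cdr3_len_nt), 33)
})

test_that("vhUsageMatrix counts once per stratum and min-max normalizes rows", {
  # one gene across 3 strata with clone counts {2, 6, 10}
  mk <- function(n, strain, gene = "IGHV1-1", offset = 0L) {
    codons <- c("GCT", "GGT", "TGT", "AAA", "CCT", "CAT", "GAT", "GAA",
                "TTT", "ATG")
    do.call(rbind, lapply(seq_len(n), function(i)
      makeRecords(strrep(codons[offset + i], 6), v_call = gene,
                  strain = strain, mouse_id = paste0(strain, "_m1"),
                  record_id = paste0(gene, strain, i))))
  }
  rec <- rbind(mk(2, "WT"), mk(6, "DKO-F"), mk(10, "DKO-M"))
  vu <- suppressWarnings(vhUsageMatrix(callClones(rec), top_n = 5))
  expect_equal(unname(vu$counts["IGHV1-1", c("WT.FoB", "DKO-F.FoB",
                                             "DKO-M.FoB")]),
               c(2L, 6L, 10L))
  expect_equal(unname(vu$normalized["IGHV1-1", c("WT.FoB", "DKO-F.FoB",
                                                 "DKO-M.FoB")]),
               c(0, 0.5, 1))
  expect_warning(vhUsageMatrix(callClones(rec), top_n = 20), "distinct V genes")
  # constant rows map to 0 and are flagged
  rec2 <- rbind(mk(4, "WT"), mk(4, "DKO-F"))
  vu2 <- suppressWarnings(vhUsageMatrix(callClones(rec2), top_n = 1))
  expect_true(all(vu2$normalized == 0))
  expect_true(vu2$constant_rows[["IGHV1-1"]])
  # top_n selection: descending total clone count, lexicographic ties
  rec3 <- rbind(mk(3, "WT", "IGHV3-3", offset = 0L),
                mk(3, "WT", "IGHV2-2", offset = 3L),
                mk(1, "WT", "IGHV1-1", offset = 6L))
  vu3 <- suppressWarnings(vhUsageMatrix(callClones(rec3), top_n = 2))
  expect_equal(rownames(vu3$counts), c("IGHV2-2", "IGHV3-3"))
})
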