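test_that("cdr3Identity counts matching positions over the common length", {
  expect_equal(cdr3Identity("CARDYW", "CARDYW"), 1.0)
  expect_equal(cdr3Identity("CARDYW", "CARDFW"), 5 / 6)
  expect_equal(cdr3Identity("CARDYWCARF", "CARDYWCARW"), 0.9)
  expect_error(cdr3Identity("CAR", "CARD"), "equal-length")
  # X matches nothing except X
  expect_equal(cdr3Identity("CX", "CY"), 0.5)
  expect_equal(cdr3Identity("CX", "CX"), 1.0)
})

test_that("identity clustering is single-linkage over the >=threshold graph", {
  same <- makeRecords(rep("TGTGCTAGAGATTACTGGGCTAGAGATTAC", 2))
  expect_equal(nClones(callClones(same)), 1L)
  # chain: A-B 0.9, B-C 0.9, A-C 0.8 at aa length 10
  a <- "GCAGCAGCAGCAGCAGCAGCAGCAGCAGCA"            # AAAAAAAAAA
  b <- "TGCGCAGCAGCAGCAGCAGCAGCAGCAGCA"            # CAAAAAAAAA
  c_ <- "TGCTGCGCAGCAGCAGCAGCAGCAGCAGCA"           # CCAAAAAAAA
  chain <- makeRecords(c(a, b, c_))
  expect_equal(nClones(callClones(chain, collapse = FALSE)), 1L)
  # complete linkage refuses the chain: max distance A-C is below threshold
  expect_gt(nClones(callClones(chain, collapse = FALSE,
                               linkage = "complete")), 1L)
  # all pairwise identities below threshold -> singletons
  singletons <- makeRecords(c("TGTGCTAGATGGGCTAGAGATTACTGGGCA",
                              "GGGCCCAAATTTGGGCCCAAATTTGGGCCC",
                              "ATGATGATGATGATGATGATGATGATGATG",
                              "CACCACCACCACCACCACCACCACCACCAC"))
  expect_equal(nClones(callClones(singletons, collapse = FALSE)), 4L)
})

test_that("records differing in V, J, CDR3 length or mouse never co-cluster", {
  nt <- "TGTGCTAGAGATTACTGG"
  rec <- rbind(
    makeRecords(nt, v_call = "IGHV1-1", record_id = "a"),
    makeRecords(nt, v_call = "IGHV1-2", record_id = "b"),
    makeRecords(nt, j_call = "IGHJ2", record_id = "c"),
    makeRecords(paste0(nt, "GCT"), record_id = "d"),
    makeRecords(nt, mouse_id = "m2", record_id = "e"))
  cs <- callClones(rec, collapse = FALSE)
  expect_equal(nClones(cs), 5L)
  # the 2-nt collapse rejoins pure gene-call differences (a, b, c) but can
  # never cross CDR3 lengths or mice
  cs2 <- callClones(rec, collapse = TRUE)
  expect_equal(nClones(cs2), 3L)
})

test_that("consensusCdr3 is the copy-weighted majority with fixed tie rules", {
  expect_equal(consensusCdr3("ACGT"), "ACGT")
  expect_equal(consensusCdr3(c("AAA", "AAG"), copies = c(3, 1)), "AAA")
  expect_equal(consensusCdr3(c("AAA", "AAC"), copies = c(1, 1)), "AAA")
  expect_equal(consensusCdr3(c("GTT", "TTT"), copies = c(1, 1)), "GTT")
  # N never wins a tie against a concrete base, but wins a strict majority
  expect_equal(consensusCdr3(c("AAN", "AAC"), copies = c(1, 1)), "AAC")
  expect_equal(consensusCdr3(c("AAN", "AAC"), copies = c(2, 1)), "AAN")
  expect_error(consensusCdr3(character()), "empty")
})

test_that("collapse merges consensus CDR3s within 2 nt across gene calls", {
  nt1 <- "TGTGCTAGAGATTACTGG"
  nt2 <- "TGTGCTAGAGATTGGTGG"  # Hamming 2 from nt1
  nt3 <- "TGTGAAAGAGATTGGTGG"  # Hamming 2 from nt2, 4 from nt1
  far <- "TGTGAACCCGATTGGTGG"  # Hamming 3 from nt3
  two <- rbind(makeRecords(nt1, v_call = "IGHV1-1", copies = 5,
                           record_id = "a"),
               makeRecords(nt2, v_call = "IGHV9-9", record_id = "b"))
  cs <- callClones(two)
  expect_equal(nClones(cs), 1L)
  # dominant clone's gene calls win
  expect_equal(clones(cs)$v_call, "IGHV1-1")
  expect_equal(nClones(callClones(rbind(
    makeRecords(nt3, record_id = "a"),
    makeRecords(far, v_call = "IGHV9-9", record_id = "b")))), 2L)
  # transitive chain nt1 - nt2 - nt3 merges despite d(nt1, nt3) = 4
  chain <- rbind(makeRecords(nt1, v_call = "IGHV1-1", record_id = "a"),
                 makeRecords(nt2, v_call = "IGHV2-1", record_id = "b"),
                 makeRecords(nt3, v_call = "IGHV3-1", record_id = "c"))
  expect_equal(nClones(callClones(chain)), 1L)
  expect_equal(nClones(callClones(chain, collapse = FALSE)), 3L)
})

test_that("clone calling matches the brute-force oracle on random instances", {
  for (seed in 1:150) {
    rec <- randomInstance(seed)
    cs <- callClones(rec)
    want <- oracleClones(rec)
    expect_equal(cloneSetSignature(cs),
                 partitionSignature(rec$record_id, want),
                 label = paste("seed", seed))
  }
})

test_that("single records and empty input behave per contract", {
  one <- makeRecords("TGTGCTAGATGG")
  cs <- callClones(one)
  expect_equal(nClones(cs), 1L)
  expect_equal(clones(cs)$consensus_cdr3_nt, "TGTGCTAGATGG")
  expect_equal(clones(cs)$total_copies, 1L)
  expect_error(callClones(one[0, ]), "zero records")
})

test_that("clone ids are deterministic: descending copies then consensus", {
  rec <- rbind(
    makeRecords("TGTGCTAGATGG", copies = 2, record_id = "a"),
    makeRecords("GGGCCCAAATTT", copies = 7, record_id = "b"),
    makeRecords("ATGATGATGATG", copies = 7, record_id = "c"))
  cl <- clones(callClones(rec))
  expect_equal(cl$total_copies, c(7L, 7L, 2L))
  # tie at 7 copies broken by consensus string order
  expect_equal(cl$consensus_cdr3_nt[1:2],
               sort(c("GGGCCCAAATTT", "ATGATGATGATG")))
})

test_that("lowering the identity threshold never increases the clone count", {
  for (seed in 1:40) {
    rec <- randomInstance(seed)
    n_hi <- nClones(callClones(rec, threshold = 0.95, collapse = FALSE))
    n_mid <- nClones(callClones(rec, threshold = 0.85, collapse = FALSE))
    n_lo <- nClones(callClones(rec, threshold = 0.60, collapse = FALSE))
    expect_true(n_hi >= n_mid && n_mid >= n_lo, label = paste("seed", seed))
  }
})

test_that("CloneSet validity catches inconsistent construction", {
  cs <- callClones(makeRecords(c("TGTGCTAGATGG", "TGTGCTAGATGG")))
  bad <- clones(cs)
  bad$total_copies <- bad$total_copies + 1L
  expect_error(methods::new("CloneSet", clones = bad,
                            records = cloneRecords(cs),
                            params = cloneParams(cs)),
               "total_copies")
})

test_that("clone table carries per-sample copy columns that sum to totals", {
  rec <- rbind(
    makeRecords("TGTGCTAGATGG", copies = 3, subset = "ABC", replicate = 1,
                record_id = "a"),
    makeRecords("TGTGCTAGATGG", copies = 2, subset = "ABC", replicate = 2,
                record_id = "b"),
    makeRecords("TGTGCTAGATGG", copies = 4, subset = "PB_CD11cpos",
                replicate = 1, record_id = "c"))
  ct <- cloneTable(callClones(rec))
  expect_equal(nrow(ct), 1L)
  sample_cols <- grep("rep", names(ct), value = TRUE)
  expect_equal(sum(unlist(ct[sample_cols])), ct$total_copies)
  expect_equal(ct[["m1.ABC.rep1"]], 3L)
  expect_equal(ct[["m1.PB_CD11cpos.rep1"]], 4L)
})
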