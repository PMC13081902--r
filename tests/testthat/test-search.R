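test_that("six-frame translation follows the standard code with X for ambiguity", {
  fr <- sixFrameTranslate("ATGGCC")
  expect_equal(unname(fr["+1"]), "MA")
  expect_equal(unname(sixFrameTranslate("TAATAG")["+1"]), "**")
  expect_equal(unname(sixFrameTranslate("ATNGCC")["+1"]), "XA")
  expect_warning(fr0 <- sixFrameTranslate("AT"), "shorter")
  expect_true(all(fr0 == ""))
  expect_error(sixFrameTranslate("ATGQ"), "invalid nucleotide")
})

test_that("reverse-complementing a read swaps the plus and minus frame sets", {
  set.seed(71)
  read <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  f1 <- sixFrameTranslate(read)
  f2 <- sixFrameTranslate(rc)
  expect_equal(unname(f1[c("+1", "+2", "+3")]), unname(f2[c("-1", "-2", "-3")]))
  expect_equal(unname(f1[c("-1", "-2", "-3")]), unname(f2[c("+1", "+2", "+3")]))
})

test_that("frame lengths and residues match an independent codon-table oracle", {
  set.seed(73)
  read <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  frames <- sixFrameTranslate(read)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  gc <- Biostrings::GENETIC_CODE
  for (f in 1:3) {
    for (src in c("fwd", "rev")) {
      nt <- if (src == "fwd") read else rc
      lab <- if (src == "fwd") paste0("+", f) else paste0("-", f)
      ncod <- floor((300 - (f - 1)) / 3)
      expect_equal(nchar(frames[[lab]]), ncod)
      codons <- substring(nt, seq(f, by = 3, length.out = ncod),
                          seq(f + 2, by = 3, length.out = ncod))
      expect_equal(frames[[lab]], paste(gc[codons], collapse = ""))
    }
  }
})

test_that("error-free reads hit their source gene at exactly 100% identity", {
  set.seed(79)
  fx <- make_tiny_study_db()
  g <- "t2"
  read <- substr(fx$cds[[g]], 31, 150) # in-frame +1? arbitrary offset
  hits <- searchReads(c(r1 = read), fx$db)
  own <- hits[hits$target_id == g, ]
  expect_gte(nrow(own), 1L)
  expect_equal(max(own$identity_pct), 100)
})

test_that("reads sharing no k-mer with the database produce no hits", {
  db <- referenceDB(c(k1 = strrep("K", 100)))
  # poly-proline read: CCX codons translate to P in every frame
  hits <- searchReads(c(r1 = strrep("CCC", 40)), db)
  expect_equal(nrow(hits), 0L)
})

test_that("prefiltered hits agree with the exhaustive no-prefilter search", {
  set.seed(83)
  fx <- make_tiny_study_db(nTargets = 2, nDecoys = 3, len = 90)
  ab <- stats::setNames(rep(1 / 5, 5), names(fx$cds))
  sim <- simulateMetagenome(fx$cds, ab, nReads = 40, readLen = 120,
                            errorRate = 0.02)
  pre <- searchReads(sim$reads, fx$db)
  full <- searchReads(sim$reads, fx$db, prefilter = FALSE)
  key <- function(h) paste(h$read_id, h$target_id, h$frame)
  # every prefiltered hit is in the exhaustive set with identical stats
  expect_true(all(key(pre) %in% key(full)))
  mfull <- full[match(key(pre), key(full)), ]
  expect_equal(pre$score, mfull$score)
  expect_equal(pre$identity_pct, mfull$identity_pct)
  # the high-identity source hits survive the prefilter
  bestf <- full[full$identity_pct > 90, ]
  expect_true(all(key(bestf) %in% key(pre)))
})

test_that("best-hit assignment enforces the strict identity cutoff and decoy exclusion", {
  mk <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    df
  }
  # single surviving target hit is assigned
  h1 <- mk(read_id = "r1", target_id = "t1", identity_pct = 95,
           score = 100, is_decoy = FALSE)
  m1 <- assignBest(h1)
  expect_equal(nrow(assignedHits(m1)), 1L)
  # decoy at higher identity than the target: read discarded and counted
  h2 <- mk(read_id = c("r1", "r1"), target_id = c("d1", "t1"),
           identity_pct = c(95, 92), score = c(80, 100),
           is_decoy = c(TRUE, FALSE))
  m2 <- assignBest(h2)
  expect_equal(nrow(assignedHits(m2)), 0L)
  expect_equal(nDecoyBest(m2), 1L)
  # identity exactly at the cutoff is excluded (strict >)
  h3 <- mk(read_id = "r1", target_id = "t1", identity_pct = 90,
           score = 100, is_decoy = FALSE)
  m3 <- assignBest(h3)
  expect_equal(nrow(assignedHits(m3)), 0L)
  expect_equal(m3@nFilteredIdentity, 1L)
  # ties on identity resolve by score, then smallest target id
  h4 <- mk(read_id = rep("r1", 3), target_id = c("t3", "t2", "t1"),
           identity_pct = c(95, 95, 95), score = c(120, 120, 90),
           is_decoy = FALSE)
  expect_equal(assignedHits(assignBest(h4))$target_id, "t2")
})

test_that("assignment rules behave monotonically and deterministically", {
  set.seed(89)
  fx <- make_tiny_study_db(nTargets = 3, nDecoys = 4, len = 100)
  ab <- stats::setNames(rep(1 / 7, 7), names(fx$cds))
  sim <- simulateMetagenome(fx$cds, ab, nReads = 120, readLen = 120,
                            errorRate = 0.02)
  hits <- searchReads(sim$reads, fx$db)
  n90 <- nrow(assignedHits(assignBest(hits, 90)))
  n95 <- nrow(assignedHits(assignBest(hits, 95)))
  expect_lte(n95, n90) # raising the cutoff never adds reads
  # removing decoys never decreases per-target counts
  withd <- tallyCounts(assignBest(hits, 90), targetIds(fx$db))
  nod <- tallyCounts(assignBest(hits[!hits$is_decoy, ], 90),
                     targetIds(fx$db))
  expect_true(all(nod >= withd))
  # determinism
  expect_identical(assignedHits(assignBest(hits, 90)),
                   assignedHits(assignBest(hits, 90)))
})

test_that("simulated reads with 1% error are assigned to their true source", {
  set.seed(97)
  fx <- make_tiny_study_db(nTargets = 3, nDecoys = 5, len = 120)
  ab <- stats::setNames(rep(1 / 8, 8), names(fx$cds))
  sim <- simulateMetagenome(fx$cds, ab, nReads = 250, readLen = 150,
                            errorRate = 0.01)
  mp <- assignBest(searchReads(sim$reads, fx$db),
                   nReadsTotal = length(sim$reads))
  a <- as.data.frame(assignedHits(mp))
  truth <- sim$truth$gene[match(a$read_id, sim$truth$read_id)]
  expect_gte(mean(a$target_id == truth), 0.95)
  expect_true(all(a$identity_pct > 90))
})

test_that("hits export as a 12-column BLAST-like table", {
  set.seed(101)
  fx <- make_tiny_study_db(nTargets = 2, nDecoys = 2, len = 90)
  read <- substr(fx$cds[["t1"]], 10, 129)
  hits <- searchReads(c(r1 = read), fx$db)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeHitsTable(hits, path)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(ncol(tab), 12L)
  expect_equal(nrow(tab), nrow(hits))
  expect_true(all(is.na(tab$V11))) # the evalue column is emitted as "NA"
})
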