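test_that("SSN edges respect both thresholds and trivial cutoffs give complete/empty graphs", {
  set.seed(41)
  seqs <- stats::setNames(replicate(5, rand_seq(40)), paste0("s", 1:5))
  pw <- allPairsAlign(seqs)
  below <- min(pw$score) - 1
  above <- max(pw$score) + 1
  g1 <- buildSSN(seqs, minIdentity = 0, scoreCutoff = below)
  expect_equal(nrow(ssnEdges(g1)), choose(5, 2))
  g2 <- buildSSN(seqs, minIdentity = 0, scoreCutoff = above)
  expect_equal(nrow(ssnEdges(g2)), 0L)
  # every retained edge satisfies both thresholds
  mid <- stats::median(pw$score)
  g3 <- buildSSN(seqs, minIdentity = 20, scoreCutoff = mid)
  e <- ssnEdges(g3)
  expect_true(all(e$score >= mid & e$identity >= 20))
  # raising the cutoff only removes edges
  g4 <- buildSSN(seqs, minIdentity = 20, scoreCutoff = mid + 5)
  expect_lte(nrow(ssnEdges(g4)), nrow(e))
  expect_error(buildSSN(c(a = "ACD", a = "ACD")), "unique")
})

test_that("two identity blocks resolve into two components matching a BFS oracle", {
  set.seed(47)
  a0 <- rand_seq(60)
  b0 <- rand_seq(60)
  blockA <- c(a0, mutateToIdentity(a0, 80), mutateToIdentity(a0, 80))
  blockB <- c(b0, mutateToIdentity(b0, 80), mutateToIdentity(b0, 80))
  seqs <- stats::setNames(c(blockA, blockB), c("a1", "a2", "a3", "b1", "b2", "b3"))
  ssn <- buildSSN(seqs, minIdentity = 50, scoreCutoff = 0)
  comp <- igraph::count_components(ssn@graph)
  expect_equal(comp, 2L)
  got <- sort(extractCluster(ssn, "a1"))
  expect_equal(got, c("a1", "a2", "a3"))
  # independent BFS over the edge list finds the same member set
  expect_equal(got, bfs_component(ssnEdges(ssn), ssnNodes(ssn), "a1"))
  # components partition the node set
  all_members <- sort(unlist(lapply(c("a1", "b1"), extractCluster, ssn = ssn)))
  expect_equal(all_members, sort(names(seqs)))
})

test_that("cluster extraction handles edgeless and complete graphs and unknown seeds", {
  set.seed(53)
  seqs <- stats::setNames(replicate(4, rand_seq(30)), paste0("s", 1:4))
  pw <- allPairsAlign(seqs)
  lone <- buildSSN(seqs, minIdentity = 0, scoreCutoff = max(pw$score) + 1)
  expect_equal(extractCluster(lone, "s2"), "s2")
  full <- buildSSN(seqs, minIdentity = 0, scoreCutoff = min(pw$score) - 1)
  expect_equal(sort(extractCluster(full, "s2")), sort(names(seqs)))
  expect_error(extractCluster(full, "nope"), "not found")
})

test_that("greedy clustering partitions sequences and picks the score-sum representative", {
  set.seed(59)
  # all-identical collapses to one cluster
  same <- stats::setNames(rep(rand_seq(30), 3), c("x", "y", "z"))
  cl <- greedyCluster(same, identityThreshold = 65)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members, c("x", "y", "z"))
  # threshold 100 on distinct sequences gives all singletons
  distinct <- stats::setNames(replicate(4, rand_seq(30)), paste0("u", 1:4))
  expect_length(greedyCluster(distinct, identityThreshold = 100), 4L)
  # 3 related + 2 unrelated: sizes 3,1,1 and the representative maximizes
  # the summed pairwise score, recomputed here independently
  base <- rand_seq(60)
  trio <- c(t1 = base, t2 = mutateToIdentity(base, 85),
            t3 = mutateToIdentity(base, 85))
  seqs <- c(trio, o1 = rand_seq(55), o2 = rand_seq(65))
  cl <- greedyCluster(seqs, identityThreshold = 65)
  sizes <- unname(sort(vapply(cl, function(x) length(x$members), integer(1))))
  expect_equal(sizes, c(1L, 1L, 3L))
  big <- cl[[which(vapply(cl, function(x) length(x$members), integer(1)) == 3)]]
  pw <- allPairsAlign(seqs[big$members])
  tot <- vapply(big$members, function(id)
    sum(pw$score[pw$id_a == id | pw$id_b == id]), numeric(1))
  expect_equal(big$representative, names(which.max(tot)))
  # partition property: every input appears exactly once
  expect_setequal(unlist(lapply(cl, `[[`, "members")), names(seqs))
})

test_that("key-residue check detects truncation and point mutations, ignoring other sites", {
  set.seed(61)
  ref <- randomProtein(600)
  prof <- keyResidueProfile()
  allpos <- c(as.integer(names(prof$metal)), as.integer(names(prof$substrate)))
  ch <- strsplit(ref, "")[[1]]
  ch[as.integer(names(prof$metal))] <- prof$metal
  ch[as.integer(names(prof$substrate))] <- prof$substrate
  ref <- paste(ch, collapse = "")

  self <- checkKeyResidues(ref, ref, prof)
  expect_true(self$pass)
  expect_true(all(self$report$present))

  # truncation before the last metal ligand removes part of the metal centre
  trunc <- substr(ref, 1, 560)
  tr <- checkKeyResidues(trunc, ref, prof)
  expect_false(tr$pass)
  expect_false(tr$report$present[tr$report$position == 583])

  # single substitution at a metal position fails with exactly one absence
  ch2 <- strsplit(ref, "")[[1]]
  ch2[441] <- "A"
  mut <- checkKeyResidues(paste(ch2, collapse = ""), ref, prof)
  expect_false(mut$pass)
  expect_equal(mut$report$position[!mut$report$present], 441L)

  # mutations outside profile columns leave the report unchanged
  free <- setdiff(seq_len(600), allpos)
  ch3 <- strsplit(ref, "")[[1]]
  for (p in sample(free, 30)) ch3[p] <- sample(setdiff(AA20, ch3[p]), 1)
  other <- checkKeyResidues(paste(ch3, collapse = ""), ref, prof)
  expect_true(other$pass)
  expect_equal(other$report$present, self$report$present)

  # substrate set can be waived
  ch4 <- strsplit(ref, "")[[1]]
  ch4[194] <- "A"
  cand <- paste(ch4, collapse = "")
  expect_false(checkKeyResidues(cand, ref, prof)$pass)
  expect_true(checkKeyResidues(cand, ref, prof, requireSubstrate = FALSE)$pass)

  expect_error(checkKeyResidues(ref, substr(ref, 1, 100), prof), "beyond")
})

test_that("reference database assembly splits targets and decoys by count arithmetic", {
  set.seed(67)
  seqs <- stats::setNames(replicate(10, rand_seq(40)), paste0("p", 1:10))
  members <- c("p1", "p2", "p3", "p4")
  reports <- stats::setNames(
    lapply(members, function(id) list(pass = id != "p4")), members)
  db <- assembleReferenceDB(members, seqs, reports)
  expect_equal(sort(targetIds(db)), c("p1", "p2", "p3"))
  expect_length(decoyIds(db), 7L)
  expect_length(db, 10L)
  # all pass, cluster covers everything -> no decoys
  allrep <- stats::setNames(lapply(names(seqs), function(i) list(pass = TRUE)),
                            names(seqs))
  expect_length(decoyIds(assembleReferenceDB(names(seqs), seqs, allrep)), 0L)
  # empty cluster -> everything is a decoy (warning, not error)
  expect_warning(db0 <- assembleReferenceDB(character(), seqs, list()),
                 "no cluster member")
  expect_length(decoyIds(db0), 10L)
})
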