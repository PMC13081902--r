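test_that("Spearman correlation handles monotone, tied and degenerate inputs", {
  x <- 1:20
  expect_equal(spearmanTest(x, x^3)$rho, 1)
  expect_equal(spearmanTest(x, -sqrt(x))$rho, -1)
  # tied data equal the rank-then-Pearson oracle
  set.seed(127)
  for (i in 1:50) {
    a <- sample(1:6, 20, TRUE)
    b <- sample(1:6, 20, TRUE)
    st <- spearmanTest(a, b)
    if (st$degenerate) next
    expect_equal(st$rho, stats::cor(rank(a), rank(b)))
    tv <- st$rho * sqrt((20 - 2) / (1 - st$rho^2))
    expect_equal(st$p, max(2 * stats::pt(-abs(tv), 18), .Machine$double.xmin))
    # rho agrees with the reference implementation
    expect_equal(st$rho, unname(suppressWarnings(
      stats::cor.test(a, b, method = "spearman", exact = FALSE)$estimate)))
  }
  expect_error(spearmanTest(1:3, 1:3), "at least 4")
  dg <- spearmanTest(rep(1, 6), 1:6)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
  # missing pairs are dropped pairwise
  st <- spearmanTest(c(1, 2, NA, 4, 5, 6), c(2, 4, 5, NA, 10, 12))
  expect_equal(st$n, 4L)
  expect_equal(st$rho, 1)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(131)
  x <- rlnorm(60); y <- rlnorm(60)
  base <- spearmanTest(x, y)$rho
  expect_equal(spearmanTest(log2(x + 0.01), y)$rho, base)
  expect_equal(spearmanTest(x, log10(y + 0.5))$rho, base)
  expect_equal(spearmanTest(exp(x), y^3)$rho, base)
})

test_that("BH adjustment reproduces the manual step-up on fixed and random inputs", {
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  set.seed(137)
  for (i in 1:200) {
    p <- runif(sample(2:12, 1))^2
    adj <- bhAdjust(p)
    expect_equal(adj, bh_stepup(p))
    expect_true(all(adj <= 1) && all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12)) # order-consistent
  }
  expect_error(bhAdjust(c(0.1, 0)), "0, 1")
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("chi-square of equal proportions matches closed-form and cell-sum oracles", {
  eq <- chiSquareProportions(c(10, 20), c(50, 100))
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  set.seed(139)
  for (i in 1:200) {
    n <- sample(20:200, 2)
    d <- c(sample(1:(n[1] - 1), 1), sample(1:(n[2] - 1), 1))
    res <- chiSquareProportions(d, n)
    a <- d[1]; b <- n[1] - d[1]; c2 <- d[2]; dd <- n[2] - d[2]
    N <- sum(n)
    closed <- N * (a * dd - b * c2)^2 /
      ((a + b) * (c2 + dd) * (a + c2) * (b + dd))
    expect_equal(res$chi2, closed)
    expect_equal(res$df, 1)
  }
  # three groups against an independent observed-vs-expected sum
  d3 <- c(12, 30, 9); n3 <- c(40, 60, 50)
  res3 <- chiSquareProportions(d3, n3)
  tab <- rbind(d3, n3 - d3)
  expc <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res3$chi2, sum((tab - expc)^2 / expc))
  expect_equal(res3$df, 2)
  # p decreases as proportions diverge at fixed n
  pA <- chiSquareProportions(c(25, 25), c(50, 50))$p
  pB <- chiSquareProportions(c(35, 15), c(50, 50))$p
  pC <- chiSquareProportions(c(45, 5), c(50, 50))$p
  expect_true(pA > pB && pB > pC)
  expect_error(chiSquareProportions(c(0, 0), c(10, 10)), "degenerate")
})

test_that("half-minimum pseudo-count uses the dataset-wide minimum non-zero value", {
  r <- halfMinPseudocount(c(0, 2, 4))
  expect_equal(r$pseudocount, 1)
  expect_equal(r$values, c(1, 3, 5))
  # no zeros: still min/2 added uniformly
  r2 <- halfMinPseudocount(c(4, 8))
  expect_equal(r2$pseudocount, 2)
  expect_equal(r2$values, c(6, 10))
  # random sparse matrices vs a direct scan oracle
  set.seed(149)
  for (i in 1:50) {
    m <- matrix(rbinom(30, 1, 0.5) * runif(30, 0.1, 9), 5)
    if (all(m == 0)) next
    r3 <- halfMinPseudocount(m)
    expect_equal(r3$pseudocount, min(m[m > 0]) / 2)
  }
  # log layers
  lg <- halfMinPseudocount(c(0, 2, 4), logBase = 2)
  expect_equal(lg$values, log2(c(1, 3, 5)))
  lg10 <- halfMinPseudocount(c(0, 2, 4), logBase = 10)
  expect_equal(lg10$values, log10(c(1, 3, 5)))
  # per-column scope
  mc <- matrix(c(0, 2, 4, 0, 10, 20), ncol = 2)
  rc <- halfMinPseudocount(mc, scope = "column")
  expect_equal(unname(rc$pseudocount), c(1, 5))
  expect_error(halfMinPseudocount(matrix(0, 2, 2)), "non-zero")
})

test_that("multi-omic correlation pairs samples, adjusts across the panel, and detects self-correlation", {
  set.seed(151)
  ab <- stats::setNames(rlnorm(30), paste0("s", 1:30))
  mets <- cbind(self = ab, noise1 = rlnorm(30), noise2 = rlnorm(30))
  rownames(mets) <- names(ab)
  res <- correlateMultiomics(ab, mets)
  self <- res[res$metabolite_id == "self", ]
  expect_equal(self$rho, 1)
  expect_equal(self$p_adj, min(res$p_adj))
  expect_equal(res$p_adj, bhAdjust(res$p_raw))
  # unmatched samples are dropped; too few pairs warns and returns empty
  expect_warning(
    empty <- correlateMultiomics(ab[1:3],
                                 mets[10:12, , drop = FALSE]),
    "paired")
  expect_equal(nrow(empty), 0L)
})

test_that("permuted metabolites show no association at n = 200", {
  set.seed(157)
  small <- 0
  for (rep in 1:10) {
    ab <- stats::setNames(rlnorm(200), paste0("s", 1:200))
    met <- matrix(sample(ab), ncol = 1,
                  dimnames = list(names(ab), "perm"))
    res <- correlateMultiomics(ab, met)
    if (abs(res$rho) < 0.2) small <- small + 1
    expect_gt(res$p_adj, 1e-4)
  }
  expect_gte(small, 9)
})

test_that("group prevalence test combines presence calls with the chi-square", {
  pres <- stats::setNames(c(rep(TRUE, 18), rep(FALSE, 2),
                            rep(TRUE, 5), rep(FALSE, 15)),
                          paste0("s", 1:40))
  grp <- stats::setNames(rep(c("ibd", "ctrl"), each = 20), paste0("s", 1:40))
  pv <- prevalenceTest(pres, grp)
  expect_equal(pv$table$n_detected[pv$table$group == "ibd"], 18L)
  expect_equal(pv$table$prevalence[pv$table$group == "ctrl"], 0.25)
  ref <- chiSquareProportions(c(5, 18), c(20, 20))
  expect_equal(pv$chi2, ref$chi2)
  expect_lt(pv$p, 0.01)
})
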