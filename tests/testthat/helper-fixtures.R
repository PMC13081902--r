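# shared fixture builders; everything is generated in code under fixed seeds

AA4 <- c("A", "C", "D", "E")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# manual BFS used as an independent oracle for connected components
bfs_component <- function(edges, nodes, seed) {
  adj <- lapply(stats::setNames(nm = nodes), function(x) character())
  for (i in seq_len(nrow(edges))) {
    a <- edges$id_a[i]; b <- edges$id_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- seed
  queue <- seed
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- setdiff(adj[[cur]], seen)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  sort(seen)
}

# manual BH step-up used as the oracle for bhAdjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * ps[i] / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# tiny target+decoy database with matching coding sequences
make_tiny_study_db <- function(nTargets = 3, nDecoys = 5, len = 120) {
  anc <- randomProtein(len)
  targets <- c(anc, vapply(seq_len(nTargets - 1),
                           function(i) mutateToIdentity(anc, 70),
                           character(1)))
  names(targets) <- paste0("t", seq_len(nTargets))
  decoys <- vapply(seq_len(nDecoys), function(i) randomProtein(len),
                   character(1))
  names(decoys) <- paste0("d", seq_len(nDecoys))
  list(db = referenceDB(targets, decoys),
       cds = vapply(c(targets, decoys), reverseTranslate, character(1)))
}
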