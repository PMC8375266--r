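# Shared fixtures, built in code at test time.

# two disjoint k-cliques, optionally bridged by one edge to keep the graph
# connected for encoders that need it
twoCliqueNetwork <- function(k = 8, bridge = FALSE, seeds = character()) {
  ids <- sprintf("N%02d", seq_len(2 * k))
  cl1 <- t(combn(ids[1:k], 2))
  cl2 <- t(combn(ids[(k + 1):(2 * k)], 2))
  ed <- rbind(cl1, cl2)
  if (bridge) ed <- rbind(ed, c(ids[k], ids[k + 1]))
  geneNetwork(data.frame(a = ed[, 1], b = ed[, 2]), nodes = ids,
              seeds = seeds)
}

# minimal valid COJO .ma content
writeMaFixture <- function(path, rows) {
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tse\tp\tN", rows), path)
}

writeEqtlFixture <- function(path, rows) {
  writeLines(c("SNP\tgene\tA1\tA2\tb\tse\tp", rows), path)
}

# brute-force AUC over all positive-negative score pairs (ties = 1/2);
# the independent oracle for the ROC integrator
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
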