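# Small in-code fixtures shared across test files.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny weighted network built directly (bypassing file IO).
make_network <- function(edges, weights) {
  genes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  structure(list(genes = genes, edges = edges,
                 weights = weights[genes], graph = g),
            class = "weighted_network")
}

# Path graph A-B, unit weights: the 2x2 textbook diffusion example.
two_node_network <- function(w = c(A = 1, B = 1)) {
  make_network(data.frame(from = "A", to = "B",
                          stringsAsFactors = FALSE), w)
}

# Random connected weighted network for property tests.
random_network <- function(n, p_edge = 0.15, seed) {
  set.seed(seed)
  genes <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(genes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  ord <- sample(genes)
  from <- c(pairs[1L, keep], ord[-n])
  to <- c(pairs[2L, keep], ord[-1L])
  e <- unique(data.frame(from = pmin(from, to), to = pmax(from, to),
                         stringsAsFactors = FALSE))
  w <- stats::setNames(stats::rexp(n), genes)
  make_network(e, w)
}

# Minimal genotype fixture: 3 individuals x 3 SNPs, all effect-aligned.
make_genotypes <- function(dosages, counted, other) {
  mprsnet:::new_genotype_matrix(dosages, counted, other)
}

make_sumstats <- function(snp_id, beta,
                          effect = rep("C", length(snp_id)),
                          other = rep("A", length(snp_id)),
                          chrom = rep("1", length(snp_id)),
                          pos = seq(1000, by = 1000,
                                    length.out = length(snp_id))) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect, other_allele = other, beta = beta,
             p_value = rep(0.5, length(snp_id)), stringsAsFactors = FALSE)
}

# Brute-force SCC oracle: mutual reachability via Floyd-Warshall closure.
scc_oracle <- function(S, delta) {
  n <- nrow(S)
  reach <- (S >= delta)
  reach <- t(reach)            # edge j -> i iff S[i, j] >= delta
  diag(reach) <- TRUE
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
    }
  }
  mutual <- reach & t(reach)
  comp <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      label <- label + 1L
      comp[mutual[i, ]] <- label
    }
  }
  comp
}

# Two partitions are equal up to relabelling.
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
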