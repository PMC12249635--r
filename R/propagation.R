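#' Random-walk-with-restart similarity matrix
#'
#' Builds the asymmetric joint similarity matrix that combines network
#' topology and node weights. With column-stochastic transition matrix
#' W = A D^-1 and restart probability beta, two conventions are offered:
#'
#' * `hotnet2` (default): S = beta (I - (1 - beta) W)^-1 diag(w) — the
#'   insulated heat-diffusion operator used by the HotNet family. It is
#'   invertible for every beta in (0, 1) and conserves heat: column j of S
#'   sums to w_j.
#' * `literal`: S = (beta I - (1 - beta) W)^-1 diag(w). Because W has
#'   eigenvalue 1, beta I - (1 - beta) W is singular at beta = 0.5 on any
#'   connected graph (and ill-conditioned nearby); a condition-number guard
#'   raises an informative error rather than returning noise.
#'
#' @param network A connected `weighted_network` (degrees >= 1).
#' @param beta Restart probability in (0, 1); default 0.4.
#' @param convention `"hotnet2"` or `"literal"`.
#' @return A `diffusion_model`: list with `S`, the weight-free kernel `K`
#'   (so `S = K diag(w)`), `beta`, `convention`, `genes`, `weights`.
#' @export
compute_similarity_matrix <- function(network, beta = 0.4,
                                      convention = c("hotnet2", "literal")) {
  convention <- match.arg(convention)
  assert_that(beta > 0 && beta < 1, "beta must lie in (0, 1)")
  A <- as.matrix(igraph::as_adjacency_matrix(network$graph, sparse = FALSE))
  A <- A[network$genes, network$genes]
  d <- colSums(A)
  assert_that(all(d >= 1), "diffusion requires every node to have degree >= 1")
  W <- sweep(A, 2L, d, "/")
  n <- nrow(W)
  if (convention == "hotnet2") {
    K <- beta * solve(diag(n) - (1 - beta) * W)
  } else {
    M <- beta * diag(n) - (1 - beta) * W
    cond <- kappa(M, exact = TRUE)
    if (!is.finite(cond) || cond > 1e12) {
      stop(sprintf(paste0(
        "beta I - (1 - beta) W is singular or ill-conditioned ",
        "(condition number %.3g): W is column-stochastic with eigenvalue 1, ",
        "so the literal operator degenerates at beta = 0.5; use beta away ",
        "from 0.5 or convention = 'hotnet2'"), cond), call. = FALSE)
    }
    K <- solve(M)
  }
  w <- network$weights[network$genes]
  S <- sweep(K, 2L, w, "*")
  dimnames(S) <- list(network$genes, network$genes)
  structure(list(S = S, K = K, beta = beta, convention = convention,
                 genes = network$genes, weights = w),
            class = "diffusion_model")
}

similarity_thresholds <- function(S) {
  vals <- S[row(S) != col(S)]
  sort(unique(vals), decreasing = TRUE)
}

#' Hierarchical clustering by strongly connected components
#'
#' Sweeps a threshold delta over the distinct off-diagonal values of S in
#' descending order. At each delta the directed graph with edge j -> i iff
#' S_ij >= delta is decomposed into strongly connected components; because
#' the edge set only grows as delta decreases, the partitions nest and the
#' sequence of merges forms a dendrogram.
#'
#' @param model A `diffusion_model`.
#' @param min_size Recorded for downstream use (default 3).
#' @param thresholds Optional threshold vector (descending); defaults to
#'   all distinct off-diagonal entries of S.
#' @return A `module_hierarchy`: `thresholds`, `membership` (thresholds x
#'   genes label matrix, each component named by its smallest member),
#'   `genes`, `n_components`, `merges` (data.frame threshold /
#'   n_components after each change), `min_size`.
#' @export
build_scc_hierarchy <- function(model, min_size = 3, thresholds = NULL) {
  S <- model$S
  assert_that(all(is.finite(S)), "similarity matrix must be finite")
  if (is.null(thresholds)) thresholds <- similarity_thresholds(S)
  membership <- .scc_memberships(unname(S), thresholds)
  colnames(membership) <- model$genes
  n_comp <- apply(membership, 1L, function(m) length(unique(m)))
  changed <- c(TRUE, diff(n_comp) != 0)
  structure(list(thresholds = thresholds, membership = membership,
                 genes = model$genes, n_components = n_comp,
                 merges = data.frame(threshold = thresholds[changed],
                                     n_components = n_comp[changed]),
                 min_size = min_size),
            class = "module_hierarchy")
}

#' Permute node weights within degree bins
#'
#' The permutation null preserves the topology and (approximately) the
#' degree-weight relationship: nodes are sorted by degree (ties broken by
#' gene id), split into bins, and weights are shuffled within each bin.
#' Bins hold at least 20 nodes — with fewer, weights could barely move and
#' the null would collapse onto the observed assignment — so the effective
#' number of bins is `min(n_bins, floor(n / 20))`, floored at 1.
#' `n_bins = 1` is a uniform permutation of all weights.
#'
#' @param network A `weighted_network`.
#' @param seed Integer seed.
#' @param n_bins Requested number of degree bins (default 100).
#' @return A `weighted_network` with permuted weights, same topology.
#' @export
permute_node_weights <- function(network, seed, n_bins = 100) {
  set.seed(seed)
  genes <- network$genes
  n <- length(genes)
  deg <- igraph::degree(network$graph)[genes]
  b <- max(1L, min(as.integer(n_bins), n %/% 20L))
  ord <- order(deg, genes)
  bin <- rep(seq_len(b), each = ceiling(n / b))[seq_len(n)]
  new_w <- network$weights
  for (k in seq_len(b)) {
    members <- genes[ord[bin == k]]
    new_w[members] <- network$weights[sample(members)]
  }
  out <- network
  out$weights <- new_w[genes]
  out
}

#' Select the cut and score candidate modules by permutation
#'
#' For each of `n_perm` degree-binned weight permutations the similarity
#' matrix is recomputed (the weight-free kernel K is reused, so each
#' permutation costs one column scaling) and the largest-SCC size is
#' evaluated at every threshold where the observed largest-SCC size
#' changes (between such jumps the observed statistic is constant while
#' the null only grows as delta falls, so each step is best tested at its
#' largest delta), giving a per-threshold empirical exceedance probability
#' p_hat(delta) = (1 + #permutations with largest SCC >= observed) /
#' (1 + n_perm). The cut delta* is the threshold carrying the largest
#' observed SCC among thresholds where that SCC is (a) significantly large
#' (p_hat < alpha) and (b) a proper submodule (size between `min_size` and
#' half the network); ties go to the largest delta. Modules are the SCCs
#' at delta* with at least `min_size` genes; each gets
#' p = (1 + #permutations with largest SCC at delta* >= module size) /
#' (1 + n_perm), and modules with p < alpha are retained. The standardized
#' deviation profile (observed - permutation mean) / (sd + 1e-12) is
#' returned for diagnostics; the methods vignette documents why it is not
#' used for cut selection.
#'
#' @param network A connected `weighted_network`.
#' @param beta Restart probability.
#' @param convention Diffusion convention (see
#'   [compute_similarity_matrix()]).
#' @param n_perm Number of permutations (>= 19; default 800).
#' @param min_size Minimum module size (default 3).
#' @param seed Integer seed (mandatory).
#' @param n_bins Degree bins for the permutation null.
#' @param side Label prefixed to module ids (e.g. `"left"` -> `left.M1`,
#'   `left.M2`, ... in decreasing size order).
#' @param alpha Retention threshold on the permutation p (default 0.05).
#' @return A `module_detection` list: `delta_star`, `modules` (data.frame
#'   with `module_id`, `side`, `genes` list-column, `perm_p`),
#'   `thresholds`, `observed_sizes`, `exceedance_p`, `z`, `perm_sizes`,
#'   `model`. When no threshold qualifies, `delta_star` is `NA` and the
#'   module table is empty.
#' @export
select_cut_and_score <- function(network, beta = 0.4,
                                 convention = "hotnet2", n_perm = 800,
                                 min_size = 3, seed, n_bins = 100,
                                 side = "trait", alpha = 0.05) {
  assert_that(!missing(seed), "a seed is mandatory")
  assert_that(n_perm >= 19, "n_perm must be >= 19")
  model <- compute_similarity_matrix(network, beta, convention)
  all_thresholds <- similarity_thresholds(model$S)
  if (length(all_thresholds) <= 1L) {
    stop("degenerate similarity matrix: all off-diagonal entries equal",
         call. = FALSE)
  }
  obs_all <- .largest_scc_sizes(unname(model$S), all_thresholds)
  # The observed largest-SCC size is a step function with at most n - 1
  # jumps. Within a constant step the permutation null only grows as delta
  # decreases, so a step qualifies iff it qualifies at its largest delta:
  # permutations need evaluating only at the jump thresholds.
  jumps <- c(TRUE, diff(obs_all) != 0L)
  thresholds <- all_thresholds[jumps]
  obs <- obs_all[jumps]
  perm_sizes <- matrix(0L, n_perm, length(thresholds))
  for (i in seq_len(n_perm)) {
    wp <- permute_node_weights(network, derive_seed(seed, paste0("perm", i)),
                               n_bins)
    S_perm <- sweep(model$K, 2L, wp$weights[model$genes], "*")
    perm_sizes[i, ] <- .largest_scc_sizes(S_perm, thresholds)
  }
  mu <- colMeans(perm_sizes)
  sdv <- apply(perm_sizes, 2L, stats::sd)
  z <- (obs - mu) / (sdv + 1e-12)
  exceedance_p <- vapply(seq_along(thresholds), function(t) {
    (1 + sum(perm_sizes[, t] >= obs[t])) / (1 + n_perm)
  }, 0)
  n <- length(model$genes)
  qualifies <- obs >= min_size & obs <= n %/% 2L & exceedance_p < alpha
  modules <- data.frame(size = integer(), perm_p = numeric())
  modules$genes <- list()
  if (any(qualifies)) {
    cand <- which(qualifies)
    cand <- cand[obs[cand] == max(obs[cand])]
    i_star <- cand[1L]  # thresholds descending: first = largest delta
    delta_star <- thresholds[i_star]
    memb <- .scc_memberships(unname(model$S), delta_star)[1L, ]
    comps <- split(model$genes, memb)
    comps <- comps[lengths(comps) >= min_size]
    exceed <- perm_sizes[, i_star]
    rows <- lapply(comps, function(genes) {
      size <- length(genes)
      data.frame(size = size,
                 perm_p = (1 + sum(exceed >= size)) / (1 + n_perm))
    })
    modules <- do.call(rbind, rows)
    modules$genes <- unname(comps)
    ord <- order(-modules$size,
                 vapply(modules$genes, min, ""))
    modules <- modules[ord, , drop = FALSE]
    modules <- modules[modules$perm_p < alpha, , drop = FALSE]
  } else {
    i_star <- NA_integer_
    delta_star <- NA_real_
  }
  n_mod <- nrow(modules)
  modules$module_id <- if (n_mod > 0L) sprintf("%s.M%d", side, seq_len(n_mod)) else character(0)
  modules$side <- rep(side, n_mod)
  rownames(modules) <- NULL
  modules <- modules[, c("module_id", "side", "size", "genes", "perm_p"),
                     drop = FALSE]
  msg_log("select_cut_and_score",
          "delta* = %.4g (threshold %s/%d), %d modules with perm p < %.3g",
          delta_star, ifelse(is.na(i_star), "none", as.character(i_star)),
          length(thresholds), n_mod, alpha)
  structure(list(delta_star = delta_star, modules = modules,
                 thresholds = thresholds, observed_sizes = obs, z = z,
                 exceedance_p = exceedance_p, perm_sizes = perm_sizes,
                 model = model, n_perm = n_perm, min_size = min_size),
            class = "module_detection")
}
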