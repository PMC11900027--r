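#' A collection of gene sets over a fixed pool
#'
#' @param sets named list of gene-identifier vectors.
#' @param pool either the pool of gene identifiers (each set must be a
#'   subset) or a single integer pool size (sets are then only checked for
#'   size).
#' @return object of class `gene_set_collection` with elements `sets` and
#'   `pool_size`.
#' @export
gene_set_collection <- function(sets, pool) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stopf("sets must be a named list")
  sets <- lapply(sets, unique)
  if (length(pool) == 1 && is.numeric(pool)) {
    pool_size <- as.integer(pool)
  } else {
    pool_size <- length(unique(pool))
    bad <- vapply(sets, function(s) !all(s %in% pool), logical(1))
    if (any(bad))
      stopf("sets not contained in the pool: %s",
            paste(names(sets)[bad], collapse = ", "))
  }
  if (pool_size < 1) stopf("pool must be non-empty")
  sizes <- lengths(sets)
  if (any(sizes > pool_size))
    stopf("a set exceeds the pool size")
  structure(list(sets = sets, pool_size = pool_size),
            class = "gene_set_collection")
}

#' Size of the all-way intersection
#'
#' @param collection a [gene_set_collection()] with at least two sets.
#' @return integer intersection size.
#' @export
observed_overlap <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) < 2) stopf("need at least two sets")
  length(Reduce(intersect, collection$sets))
}

#' Exclusive (Euler) region counts
#'
#' Every element of the union is classified by its exact membership
#' signature; all `2^k - 1` non-empty signatures are reported (zeros
#' included), written as e.g. `"A&B&!C"`.
#'
#' @param collection a [gene_set_collection()] with 1 to 10 sets.
#' @return named integer vector of region counts; the counts sum to the
#'   union size.
#' @export
euler_regions <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  k <- length(collection$sets)
  if (k < 1) stopf("need at least one set")
  if (k > 10) stopf("refusing to tabulate %d sets (2^k regions)", k)
  nm <- names(collection$sets)
  union <- unique(unlist(collection$sets, use.names = FALSE))
  member <- vapply(collection$sets, function(s) union %in% s,
                   logical(length(union)))
  if (length(union) == 1) member <- matrix(member, nrow = 1)
  signature_of <- function(flags)
    paste(ifelse(flags, nm, paste0("!", nm)), collapse = "&")
  # enumerate all non-empty signatures in a fixed order
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-(2^k), , drop = FALSE]
  combos <- combos[, rev(seq_len(k)), drop = FALSE] # set-major order
  colnames(combos) <- nm
  out <- setNames(integer(nrow(combos)),
                  apply(combos, 1, function(r) signature_of(as.logical(r))))
  if (length(union)) {
    sigs <- apply(member, 1, signature_of)
    tab <- table(sigs)
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Expected all-way overlap of independent uniform random sets
#'
#' For sets of the given sizes drawn uniformly without replacement from a
#' pool of `N` genes, the expected intersection size is, by linearity,
#' `N * prod(sizes / N)`.
#'
#' @param sizes integer vector of set sizes.
#' @param N pool size.
#' @return expected intersection size.
#' @export
expected_overlap <- function(sizes, N) {
  if (N < 1) stopf("pool size must be positive")
  if (any(sizes < 0) || any(sizes > N))
    stopf("set sizes must lie in [0, N]")
  N * prod(sizes / N)
}

#' Simulate the null distribution of the all-way overlap
#'
#' Each iteration draws every set uniformly without replacement from the
#' pool and records the size of the all-way intersection.
#'
#' @param sizes integer vector of set sizes.
#' @param N pool size.
#' @param B number of iterations.
#' @param seed RNG seed; identical seeds give identical vectors.
#' @return integer vector of `B` simulated overlap sizes.
#' @export
simulate_overlap_null <- function(sizes, N, B = 10000, seed = 1) {
  if (B < 1) stopf("B must be at least 1")
  if (any(sizes > N)) stopf("set sizes cannot exceed the pool")
  k <- length(sizes)
  with_seed(seed, {
    vapply(seq_len(B), function(b) {
      hits <- integer(N)
      for (s in sizes) {
        idx <- sample.int(N, s)
        hits[idx] <- hits[idx] + 1L
      }
      sum(hits == k)
    }, integer(1))
  })
}

#' Simulation-based overlap enrichment test
#'
#' Compares the observed all-way intersection against the simulated null,
#' with the add-one adjustment counting the observed configuration as one
#' null draw: `p = (1 + #(sim >= observed)) / (B + 1)` for enrichment (the
#' tail flips for depletion). Fold enrichment is observed over the
#' simulation mean; the analytic expectation is reported alongside and
#' substituted when the simulation mean is zero.
#'
#' @param collection a [gene_set_collection()].
#' @param B number of null iterations.
#' @param seed RNG seed.
#' @param alternative `"enrichment"` (default) or `"depletion"`.
#' @return list of class `overlap_result`: observed, expected (simulation
#'   mean), expected_analytic, expected_se, fold_enrichment, p_value, B,
#'   seed, alternative, set sizes and pool size.
#' @export
overlap_test <- function(collection, B = 10000, seed = 1,
                         alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  obs <- observed_overlap(collection)
  sizes <- lengths(collection$sets)
  N <- collection$pool_size
  sims <- simulate_overlap_null(sizes, N, B, seed)
  hits <- if (alternative == "enrichment") sum(sims >= obs)
          else sum(sims <= obs)
  expected <- mean(sims)
  analytic <- expected_overlap(sizes, N)
  fold <- if (expected > 0) obs / expected
          else if (analytic > 0) obs / analytic
          else NA_real_
  structure(list(observed = obs,
                 expected = expected,
                 expected_analytic = analytic,
                 expected_se = sd(sims) / sqrt(B),
                 fold_enrichment = fold,
                 p_value = (1 + hits) / (B + 1),
                 n_iterations = B,
                 seed = seed,
                 alternative = alternative,
                 set_sizes = sizes,
                 pool_size = N),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(paste0("Overlap of %d sets (pool %d): observed %d, ",
                     "expected %.3f (analytic %.3f, SE %.4f)\n"),
              length(x$set_sizes), x$pool_size, x$observed, x$expected,
              x$expected_analytic, x$expected_se))
  cat(sprintf("fold enrichment %.2f, %s p = %.4g (B = %d)\n",
              x$fold_enrichment, x$alternative, x$p_value, x$n_iterations))
  invisible(x)
}
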