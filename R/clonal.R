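# Desk-scale clonal-evolution reconstruction. Mutations are converted to
# cancer cell fractions under the diploid-heterozygous assumption, clustered
# with a one-dimensional Gaussian mixture (EM, k-means++-style starts, BIC
# model selection), and assembled into a clone tree by a deterministic
# constraint-based builder honouring the pigeonhole sum rule.

CCF_CAP <- 1.2
TREE_TOL <- 0.05

#' Cancer cell fractions from VAFs
#'
#' `ccf = clamp(2 * vaf / purity, 0, 1.2)` under the diploid heterozygous
#' assumption; the 1.2 cap absorbs read-sampling noise above clonality.
#'
#' @param variants data.frame with a `vaf` column (pooled VAF per variant),
#'   or a numeric vector of VAFs.
#' @param purity tumor purity in (0, 1].
#' @return input data.frame with a `ccf` column appended (or a numeric
#'   vector if a vector was given).
#' @export
#' @examples
#' estimate_ccfs(c(0.25, 0.05), purity = 0.5)  # 1.0, 0.2
estimate_ccfs <- function(variants, purity) {
  if (!is.numeric(purity) || length(purity) != 1 || purity <= 0 || purity > 1) {
    stop("estimate_ccfs: purity must be in (0, 1]", call. = FALSE)
  }
  vaf <- if (is.data.frame(variants)) variants$vaf else variants
  ccf <- pmin(pmax(2 * vaf / purity, 0), CCF_CAP)
  if (is.data.frame(variants)) {
    variants$ccf <- ccf
    variants
  } else {
    ccf
  }
}

# k-means++-style seeding on sorted 1-D data: first centre uniform, later
# centres with probability proportional to squared distance to the nearest
# chosen centre.
kmeanspp_centers <- function(x, k) {
  centers <- x[sample.int(length(x), 1L)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
    if (sum(d2) == 0) {
      centers <- c(centers, x[sample.int(length(x), 1L)])
    } else {
      centers <- c(centers, x[sample.int(length(x), 1L, prob = d2)])
    }
  }
  centers
}

fit_gmm_1d <- function(x, k, n_starts, seed, max_iter = 200, tol = 1e-8) {
  n <- length(x)
  # Component variances are floored at sd ~0.03 on the CCF scale: read
  # sampling alone contributes at least that much noise at exome depths
  # (binomial VAF sd ~0.03 at depth 225, doubled on the CCF scale), so a
  # tighter component would model sampling artifacts, and BIC would
  # overfit spurious spike components inside real clusters.
  var_floor <- 1e-3
  best <- NULL
  for (s in seq_len(n_starts)) {
    res <- with_rng(derive_seed(seed, paste0("start", s, "k", k)), {
      mu <- kmeanspp_centers(x, k)
      sigma2 <- rep(max(stats::var(x), var_floor), k)
      w <- rep(1 / k, k)
      ll_old <- -Inf
      for (iter in seq_len(max_iter)) {
        dens <- vapply(seq_len(k), function(j) {
          w[j] * stats::dnorm(x, mu[j], sqrt(sigma2[j]))
        }, numeric(n))
        dens <- matrix(dens, nrow = n)
        rowsum_d <- pmax(rowSums(dens), 1e-300)
        ll <- sum(log(rowsum_d))
        resp <- dens / rowsum_d
        nk <- colSums(resp)
        nk <- pmax(nk, 1e-12)
        w <- nk / n
        mu <- colSums(resp * x) / nk
        sigma2 <- pmax(colSums(resp * (outer(x, mu, `-`))^2) / nk, var_floor)
        if (is.finite(ll) && abs(ll - ll_old) < tol) break
        ll_old <- ll
      }
      list(mu = mu, sigma2 = sigma2, w = w, loglik = ll)
    })
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  best
}

#' Cluster mutation CCFs with a 1-D Gaussian mixture
#'
#' Fits mixtures with k = 1..max_k components by EM (k-means++-style
#' initialization, several restarts) and selects k by the Bayesian
#' information criterion. Clusters are reported in descending mean-CCF
#' order (cluster 1 is the most clonal). Internally the data are sorted, so
#' the result is invariant to the input order of mutations.
#'
#' @param ccfs numeric vector of CCFs (or data.frame with a `ccf` column).
#' @param max_k maximum number of clusters to consider.
#' @param seed integer seed (EM restarts use seeds derived from it).
#' @param n_starts EM restarts per k.
#' @return list with `k`, `assignments` (cluster index per input mutation),
#'   `means`, `sizes`, `bic` (per k) and `model`.
#' @export
cluster_ccf <- function(ccfs, max_k = 4, seed = 1L, n_starts = 10) {
  x_in <- if (is.data.frame(ccfs)) ccfs$ccf else ccfs
  n <- length(x_in)
  if (n < 1) {
    stop("cluster_ccf: at least one mutation is required", call. = FALSE)
  }
  if (max_k < 1) {
    stop("cluster_ccf: max_k must be >= 1", call. = FALSE)
  }
  if (max_k > n) {
    message("cluster_ccf: max_k truncated to the number of mutations (", n, ")")
    max_k <- n
  }
  ord <- order(x_in)
  x <- x_in[ord]
  if (n == 1 || stats::sd(x) == 0) {
    return(list(k = 1L, assignments = rep(1L, n), means = mean(x),
                sizes = n, bic = stats::setNames(NA_real_, "1"), model = NULL))
  }
  fits <- list()
  bic <- numeric(max_k)
  for (k in seq_len(max_k)) {
    fit <- fit_gmm_1d(x, k, n_starts, derive_seed(seed, paste0("gmm_k", k)))
    fits[[k]] <- fit
    p <- 3 * k - 1
    bic[k] <- -2 * fit$loglik + p * log(n)
  }
  k_best <- which.min(bic)
  fit <- fits[[k_best]]
  # hard assignment by maximum responsibility, clusters ordered by
  # descending mean
  ord_mu <- order(fit$mu, decreasing = TRUE)
  mu <- fit$mu[ord_mu]
  sigma2 <- fit$sigma2[ord_mu]
  w <- fit$w[ord_mu]
  dens <- vapply(seq_len(k_best), function(j) {
    w[j] * stats::dnorm(x_in, mu[j], sqrt(sigma2[j]))
  }, numeric(n))
  dens <- matrix(dens, nrow = n)
  assignments <- max.col(dens, ties.method = "first")
  sizes <- tabulate(assignments, nbins = k_best)
  list(k = as.integer(k_best), assignments = assignments, means = mu,
       sizes = sizes, bic = stats::setNames(bic, seq_len(max_k)),
       model = list(mu = mu, sigma2 = sigma2, w = w))
}

#' Build a clone tree from CCF clusters
#'
#' The highest-CCF cluster is the trunk. Each remaining cluster, in
#' descending CCF order, attaches to the feasible host closest to the
#' trunk: the existing node with the LARGEST CCF that satisfies both
#' child <= parent and the pigeonhole sum rule (children's CCFs sum to at
#' most the parent's), with tolerance 0.05. Sibling placement is therefore
#' preferred whenever the sum rule permits it, and a cluster is nested
#' deeper only when the sum rule forbids siblinghood — the only direction
#' in which one-dimensional CCFs carry topology information. If no node
#' can host a cluster it attaches to the trunk as a new branch. Ties break
#' toward the lowest cluster index.
#'
#' @param clusters list with `means` (descending) and `sizes`, as returned
#'   by [cluster_ccf()].
#' @return a `subclone_tree`: list with `ccf`, `size`, `parent` (0 for the
#'   trunk) and `trunk` (= 1).
#' @export
build_tree <- function(clusters) {
  ccf <- clusters$means
  size <- clusters$sizes
  k <- length(ccf)
  if (is.unsorted(rev(ccf))) {
    ord <- order(ccf, decreasing = TRUE)
    ccf <- ccf[ord]
    size <- size[ord]
  }
  parent <- integer(k)
  if (k >= 2) {
    for (i in 2:k) {
      child_sum <- function(node) {
        kids <- which(parent[seq_len(i - 1)] == node)
        sum(ccf[kids])
      }
      feasible <- which(vapply(seq_len(i - 1), function(node) {
        ccf[i] <= ccf[node] + TREE_TOL &&
          child_sum(node) + ccf[i] <= ccf[node] + TREE_TOL
      }, logical(1)))
      if (length(feasible) == 0) {
        parent[i] <- 1L
      } else {
        best <- feasible[order(-ccf[feasible], feasible)][1]
        parent[i] <- as.integer(best)
      }
    }
  }
  tree <- list(ccf = ccf, size = size, parent = parent, trunk = 1L)
  class(tree) <- "subclone_tree"
  check_tree(tree)
  tree
}

# post-construction assertion of the structural invariants
check_tree <- function(tree) {
  k <- length(tree$ccf)
  stopifnot(sum(tree$parent == 0) == 1, tree$parent[1] == 0)
  for (i in seq_len(k)[-1]) {
    p <- tree$parent[i]
    stopifnot(tree$ccf[i] <= tree$ccf[p] + TREE_TOL)
  }
  for (node in seq_len(k)) {
    kids <- which(tree$parent == node)
    if (length(kids) > 0) {
      stopifnot(sum(tree$ccf[kids]) <= tree$ccf[node] + TREE_TOL)
    }
  }
  invisible(tree)
}

#' Classify a clone tree as branched or linear
#'
#' Branched iff some node has two or more children each containing at least
#' one mutation.
#'
#' @param tree a `subclone_tree`.
#' @return "branched" or "linear".
#' @export
classify_branching <- function(tree) {
  k <- length(tree$ccf)
  for (node in seq_len(k)) {
    kids <- which(tree$parent == node)
    kids <- kids[tree$size[kids] >= 1]
    if (length(kids) >= 2) {
      return("branched")
    }
  }
  "linear"
}

#' Map driver mutations to trunk or branch
#'
#' @param driver_calls data.frame with a `key` column.
#' @param tree a `subclone_tree`.
#' @param assignments named (by locus key) or positional cluster index per
#'   mutation; drivers are looked up by key when names are present.
#' @return driver_calls with a `position` column ("trunk"/"branch").
#' @export
map_to_trunk <- function(driver_calls, tree, assignments) {
  cl <- if (!is.null(names(assignments))) {
    assignments[driver_calls$key]
  } else {
    assignments
  }
  driver_calls$position <- ifelse(cl == tree$trunk, "trunk", "branch")
  driver_calls
}

#' Flag convergent evolution
#'
#' Genes hit by two or more distinct mutations (distinct loci) within one
#' tumor.
#'
#' @param driver_calls data.frame with tumor_id, gene, key.
#' @return data.frame of (tumor_id, gene, n_loci, loci) rows.
#' @export
detect_convergent <- function(driver_calls) {
  d <- driver_calls[!duplicated(paste(driver_calls$tumor_id,
                                      driver_calls$key)), , drop = FALSE]
  groups <- split(d$key, paste(d$tumor_id, d$gene, sep = "\r"))
  hits <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(hits) == 0) {
    return(data.frame(tumor_id = character(0), gene = character(0),
                      n_loci = integer(0), loci = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(names(hits), "\r", fixed = TRUE)
  data.frame(tumor_id = vapply(parts, `[`, character(1), 1),
             gene = vapply(parts, `[`, character(1), 2),
             n_loci = vapply(hits, length, integer(1)),
             loci = vapply(hits, paste, character(1), collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate tumor purity from the trunk cluster
#'
#' Purity is the trunk cluster's mean VAF times two (inverting the diploid
#' heterozygous VAF model for a clonal mutation), clamped to (0, 1].
#'
#' @param trunk_mean_vaf mean VAF of mutations assigned to the trunk.
#' @return purity estimate in (0, 1].
#' @export
#' @examples
#' estimate_purity(0.35)  # 0.7
estimate_purity <- function(trunk_mean_vaf) {
  min(max(2 * trunk_mean_vaf, 1e-6), 1)
}

#' Full clonal reconstruction for one tumor
#'
#' Estimates CCFs (self-estimating purity from the top VAF cluster when not
#' supplied), clusters them, builds the tree, classifies branching and maps
#' drivers.
#'
#' @param variants data.frame with `key` and `vaf` columns.
#' @param purity optional known purity; if NULL it is estimated from the
#'   highest-VAF cluster and CCFs are recomputed with the estimate.
#' @param max_k maximum cluster count.
#' @param seed integer seed.
#' @param driver_keys optional keys of driver mutations to map.
#' @return list with `purity`, `clusters`, `tree`, `branching`,
#'   `assignments` (named by key) and `driver_positions`.
#' @export
reconstruct_clones <- function(variants, purity = NULL, max_k = 4, seed = 1L,
                               driver_keys = character(0)) {
  if (nrow(variants) == 0) {
    stop("reconstruct_clones: no variants supplied", call. = FALSE)
  }
  if (is.null(purity)) {
    # provisional clustering on VAF scale to find the clonal cluster
    prov <- cluster_ccf(variants$vaf, max_k = max_k,
                        seed = derive_seed(seed, "purity"), n_starts = 5)
    trunk_vaf <- prov$means[1]
    purity <- estimate_purity(trunk_vaf)
  }
  vars <- estimate_ccfs(variants, purity)
  clusters <- cluster_ccf(vars$ccf, max_k = max_k, seed = seed)
  tree <- build_tree(clusters)
  assignments <- stats::setNames(clusters$assignments, vars$key)
  branching <- classify_branching(tree)
  driver_positions <- if (length(driver_keys) > 0) {
    dk <- driver_keys[driver_keys %in% names(assignments)]
    map_to_trunk(data.frame(key = dk, stringsAsFactors = FALSE), tree,
                 assignments)
  } else {
    NULL
  }
  list(purity = purity, clusters = clusters, tree = tree,
       branching = branching, assignments = assignments,
       driver_positions = driver_positions)
}
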