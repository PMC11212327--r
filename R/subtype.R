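# Transcriptomic immune subtyping: TMM normalization, consensus NMF with
# cophenetic rank selection, SAM gene ranking, Fisher-exact differential
# expression, single-sample gene-set (immune/stromal) scoring, IM-H/IM-L
# labelling and nearest-centroid projection onto external cohorts.

#' TMM normalization and log2-CPM
#'
#' Trimmed mean of M-values between-sample normalization: the reference is
#' the sample whose 75th-percentile count is closest to the mean of 75th
#' percentiles; each sample's factor is 2 to the weighted trimmed mean of
#' M-values against the reference (trimming `trim_m` of the M tails and
#' `trim_a` of the A tails), and factors are rescaled to geometric mean 1.
#' Normalized values are `log2(count / (libsize * factor) * 1e6 + 1)`.
#'
#' @param counts non-negative integer matrix, genes x samples (>= 2
#'   samples).
#' @param trim_m fraction of M values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A values trimmed from each tail (default 0.05).
#' @return list with `factors` (per sample), `libsize` and `logcpm`.
#' @export
tmm_normalize <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) {
    stop("tmm_normalize: at least 2 samples required", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("tmm_normalize: all-zero sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factors <- edgeR::calcNormFactors(counts, method = "TMM",
                                    logratioTrim = trim_m, sumTrim = trim_a)
  eff <- lib * factors
  logcpm <- log2(sweep(counts, 2, eff, `/`) * 1e6 + 1)
  list(factors = as.numeric(factors), libsize = as.numeric(lib),
       logcpm = logcpm)
}

#' Select the most variable genes and shift to non-negativity
#'
#' Restricts a normalized matrix to the `n_top` most variable genes and
#' subtracts the global minimum so NMF input is non-negative.
#'
#' @param logcpm normalized matrix, genes x samples.
#' @param n_top number of genes to keep.
#' @return non-negative matrix with `n_top` (or fewer) rows.
#' @export
nmf_feature_select <- function(logcpm, n_top = 1500) {
  v <- apply(logcpm, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(logcpm)))]
  m <- logcpm[sort(keep), , drop = FALSE]
  m - min(m)
}

# Multiplicative-update NMF for the Frobenius objective.
nmf_fit <- function(V, k, seed, max_iter = 200, tol = 1e-6) {
  ng <- nrow(V)
  ns <- ncol(V)
  eps <- 1e-12
  with_rng(seed, {
    W <- matrix(stats::runif(ng * k, 0.1, 1), ng, k)
    H <- matrix(stats::runif(k * ns, 0.1, 1), k, ns)
    obj_old <- Inf
    for (iter in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (iter %% 10 == 0 || iter == max_iter) {
        obj <- sum((V - W %*% H)^2)
        if (is.finite(obj_old) && (obj_old - obj) / max(obj_old, eps) < tol) {
          obj_old <- obj
          break
        }
        obj_old <- obj
      }
    }
    list(W = W, H = H, objective = obj_old,
         labels = apply(H, 2, which.max))
  })
}

#' Consensus NMF across random restarts
#'
#' For each candidate rank, runs multiplicative-update NMF from
#' `n_restarts` random starts, hard-clusters samples by the maximal
#' coefficient per column, and aggregates co-clustering frequencies into a
#' consensus matrix. Rank stability is summarized by the cophenetic
#' correlation between consensus dissimilarity and its average-linkage
#' hierarchical cophenetic distances, plus the mean silhouette width of the
#' consensus clustering.
#'
#' @param mat non-negative matrix, features x samples.
#' @param ranks candidate ranks (>= 2); ranks >= the sample count are
#'   skipped with a warning.
#' @param n_restarts NMF restarts per rank.
#' @param seed integer seed.
#' @param select_tol tolerance passed to [select_rank()].
#' @return list with `per_rank` (per rank: consensus, cophenetic,
#'   silhouette, clusters, best fit), `chosen_rank`, `clusters` (at the
#'   chosen rank) and `diagnostics` (data.frame).
#' @export
nmf_consensus <- function(mat, ranks = 2:6, n_restarts = 30, seed = 1L,
                          select_tol = 0.02) {
  if (any(mat < 0)) {
    stop("nmf_consensus: input matrix must be non-negative", call. = FALSE)
  }
  if (any(ranks < 2)) {
    stop("nmf_consensus: ranks must be >= 2", call. = FALSE)
  }
  ns <- ncol(mat)
  skip <- ranks >= ns
  if (any(skip)) {
    warning("nmf_consensus: skipping rank(s) ",
            paste(ranks[skip], collapse = ", "),
            " (not below the sample count)")
    ranks <- ranks[!skip]
  }
  if (length(ranks) == 0) {
    stop("nmf_consensus: no usable ranks", call. = FALSE)
  }
  per_rank <- list()
  for (k in ranks) {
    consensus <- matrix(0, ns, ns)
    best_fit <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- nmf_fit(mat, k, derive_seed(seed, paste0("nmf_k", k, "_r", r)))
      co <- outer(fit$labels, fit$labels, `==`)
      consensus <- consensus + co
      if (is.null(best_fit) || fit$objective < best_fit$objective) {
        best_fit <- fit
      }
    }
    consensus <- consensus / n_restarts
    dimnames(consensus) <- list(colnames(mat), colnames(mat))
    D <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(D, method = "average")
    coph <- suppressWarnings(stats::cor(D, stats::cophenetic(hc)))
    if (is.na(coph)) coph <- 0
    clusters <- stats::cutree(hc, k = k)
    sil <- if (length(unique(clusters)) >= 2) {
      mean(cluster::silhouette(clusters, dmatrix = as.matrix(D))[, "sil_width"])
    } else {
      NA_real_
    }
    per_rank[[as.character(k)]] <- list(rank = k, consensus = consensus,
                                        cophenetic = coph, silhouette = sil,
                                        clusters = clusters, fit = best_fit)
  }
  coph_by_rank <- vapply(per_rank, function(p) p$cophenetic, numeric(1))
  names(coph_by_rank) <- names(per_rank)
  chosen <- select_rank(coph_by_rank, tol = select_tol)
  diagnostics <- data.frame(
    rank = as.integer(names(per_rank)),
    cophenetic = coph_by_rank,
    silhouette = vapply(per_rank, function(p) p$silhouette, numeric(1)),
    row.names = NULL)
  list(per_rank = per_rank, chosen_rank = chosen,
       clusters = per_rank[[as.character(chosen)]]$clusters,
       diagnostics = diagnostics)
}

#' Choose the factorization rank from cophenetic coefficients
#'
#' Smallest rank whose cophenetic coefficient is within `tol` of the
#' maximum; ties break toward smaller ranks.
#'
#' @param cophenetics named numeric vector (names = ranks).
#' @param tol tolerance (default 0.02).
#' @return chosen rank (integer).
#' @export
#' @examples
#' select_rank(c(`2` = 0.99, `3` = 0.90, `6` = 0.99))  # 2
select_rank <- function(cophenetics, tol = 0.02) {
  ranks <- as.integer(names(cophenetics))
  ord <- order(ranks)
  ranks <- ranks[ord]
  coph <- cophenetics[ord]
  ranks[which(coph >= max(coph) - tol)[1]]
}

#' SAM-style moderated gene ranking with permutation p-values
#'
#' Per gene, `d = (mean2 - mean1) / (s + s0)` with the pooled standard
#' error `s` and exchangeability constant `s0` fixed at the median of
#' gene-wise standard errors. Significance comes from label permutations:
#' `p = (1 + #{|d*| >= |d|}) / (n_perm + 1)` per gene.
#'
#' @param mat normalized matrix, genes x samples.
#' @param labels two-level factor (or vector) per sample; level order
#'   defines group 1 and 2.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame per gene: d, s, p, direction ("up_in_2"/"up_in_1"),
#'   significant.
#' @export
sam_rank <- function(mat, labels, n_perm = 500, seed = 1L, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("sam_rank: exactly two groups required", call. = FALSE)
  }
  if (any(table(labels) < 2)) {
    stop("sam_rank: each group needs at least 2 samples", call. = FALSE)
  }
  g2 <- labels == levels(labels)[2]
  stat <- sam_d(mat, g2)
  d <- stat$d
  s0 <- stat$s0
  n <- ncol(mat)
  n2 <- sum(g2)
  perm_idx <- with_rng(derive_seed(seed, "sam_perms"), {
    replicate(n_perm, sample.int(n, n2))
  })
  perm_idx <- matrix(perm_idx, nrow = n2)
  exceed <- numeric(nrow(mat))
  for (b in seq_len(n_perm)) {
    gp <- rep(FALSE, n)
    gp[perm_idx[, b]] <- TRUE
    db <- sam_d(mat, gp, s0 = s0)$d
    exceed <- exceed + (abs(db) >= abs(d))
  }
  p <- (1 + exceed) / (n_perm + 1)
  data.frame(gene = rownames(mat), d = d, s = stat$s, p = p,
             direction = ifelse(d >= 0, "up_in_2", "up_in_1"),
             significant = p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

# d-statistic machinery; s0 (median of s) can be frozen across permutations
sam_d <- function(mat, g2, s0 = NULL) {
  n2 <- sum(g2)
  n1 <- sum(!g2)
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  m1 <- rowMeans(mat[, !g2, drop = FALSE])
  ss2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2)
  ss1 <- rowSums((mat[, !g2, drop = FALSE] - m1)^2)
  pooled <- (ss1 + ss2) / (n1 + n2 - 2)
  s <- sqrt((1 / n1 + 1 / n2) * pooled)
  if (is.null(s0)) s0 <- stats::median(s)
  list(d = (m2 - m1) / (s + s0), s = s, s0 = s0)
}

#' Fisher-exact differential expression on pooled counts
#'
#' Per gene, a two-sided Fisher exact test on the 2x2 table of the gene's
#' summed raw counts versus the remaining library counts in each group.
#' Genes with zero counts in both groups are excluded (messaged). Direction
#' comes from the normalized group proportions.
#'
#' @param raw_counts integer matrix, genes x samples.
#' @param labels two-level factor per sample.
#' @param alpha significance level.
#' @return data.frame per tested gene: p, direction, significant; plus
#'   attributes `n_up` / `n_down` (significant genes up/down in group 2).
#' @export
fisher_deg <- function(raw_counts, labels, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("fisher_deg: exactly two groups required", call. = FALSE)
  }
  g2 <- labels == levels(labels)[2]
  c2 <- rowSums(raw_counts[, g2, drop = FALSE])
  c1 <- rowSums(raw_counts[, !g2, drop = FALSE])
  tot2 <- sum(c2)
  tot1 <- sum(c1)
  zero <- c1 + c2 == 0
  if (any(zero)) {
    message("fisher_deg: excluding ", sum(zero), " genes with zero counts")
  }
  idx <- which(!zero)
  p <- vapply(idx, function(i) {
    tab <- matrix(c(c2[i], tot2 - c2[i], c1[i], tot1 - c1[i]), nrow = 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  prop2 <- c2[idx] / tot2
  prop1 <- c1[idx] / tot1
  out <- data.frame(gene = rownames(raw_counts)[idx], p = p,
                    direction = ifelse(prop2 >= prop1, "up_in_2", "up_in_1"),
                    significant = p < alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_up") <- sum(out$significant & out$direction == "up_in_2")
  attr(out, "n_down") <- sum(out$significant & out$direction == "up_in_1")
  out
}

#' Single-sample gene-set enrichment score
#'
#' Per sample, genes are ranked by expression and the score is the
#' normalized weighted Kolmogorov-Smirnov running-sum difference between
#' the in-set and out-of-set cumulative distributions, with in-set steps
#' weighted by rank^alpha. Invariant to monotone transforms of a sample's
#' expression.
#'
#' @param normalized_matrix genes x samples.
#' @param geneset character vector of gene ids.
#' @param alpha rank-weight exponent (default 0.25).
#' @return named numeric score per sample.
#' @export
ssgsea_score <- function(normalized_matrix, geneset, alpha = 0.25) {
  genes <- rownames(normalized_matrix)
  in_set <- genes %in% geneset
  n <- length(genes)
  if (sum(in_set) == 0) {
    stop("ssgsea_score: no gene-set genes present in the matrix",
         call. = FALSE)
  }
  if (all(in_set)) {
    warning("ssgsea_score: gene set covers all genes; score degenerate (0)")
    return(stats::setNames(rep(0, ncol(normalized_matrix)),
                           colnames(normalized_matrix)))
  }
  scores <- vapply(seq_len(ncol(normalized_matrix)), function(j) {
    x <- normalized_matrix[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    inset_ord <- in_set[ord]
    w <- abs(r[ord])^alpha * inset_ord
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset_ord) / (n - sum(in_set))
    sum(p_in - p_out) / (n - 1)
  }, numeric(1))
  stats::setNames(scores, colnames(normalized_matrix))
}

#' Immune/stromal infiltration scores and a purity proxy
#'
#' ssGSEA scores for the immune and stromal signatures plus a purity proxy
#' defined as the negative of their sum, min-max rescaled to [0, 1]
#' (tumors with more infiltrate get a lower proxy; only the ordering is
#' meaningful).
#'
#' @param logcpm normalized matrix.
#' @param immune_geneset,stromal_geneset character vectors.
#' @return data.frame per sample: immune_score, stromal_score,
#'   purity_proxy.
#' @export
estimate_infiltration <- function(logcpm, immune_geneset, stromal_geneset) {
  imm <- ssgsea_score(logcpm, immune_geneset)
  str <- ssgsea_score(logcpm, stromal_geneset)
  raw <- -(imm + str)
  rng <- range(raw)
  proxy <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else rep(0.5, length(raw))
  data.frame(sample = colnames(logcpm), immune_score = unname(imm),
             stromal_score = unname(str), purity_proxy = unname(proxy),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marker-mean cell-type scores
#'
#' Arithmetic mean of normalized log2 expression over each cell type's
#' marker genes present in the matrix (markers absent are messaged).
#'
#' @param normalized_matrix genes x samples.
#' @param marker_sets named list of marker gene vectors.
#' @return matrix, cell types x samples.
#' @export
marker_score <- function(normalized_matrix, marker_sets) {
  out <- t(vapply(names(marker_sets), function(nm) {
    markers <- marker_sets[[nm]]
    present <- intersect(markers, rownames(normalized_matrix))
    if (length(present) < length(markers)) {
      message("marker_score: ", nm, ": ",
              length(markers) - length(present), " markers absent")
    }
    if (length(present) == 0) {
      return(rep(NA_real_, ncol(normalized_matrix)))
    }
    colMeans(normalized_matrix[present, , drop = FALSE])
  }, numeric(ncol(normalized_matrix))))
  colnames(out) <- colnames(normalized_matrix)
  out
}

#' Label clusters as immune-high / immune-low
#'
#' The cluster with the higher mean immune score becomes IM-H. Exactly
#' equal means are ambiguous and require a manual override.
#'
#' @param clusters integer cluster index (1/2) per sample, named.
#' @param immune_scores numeric per sample, aligned with `clusters`.
#' @param override optional cluster index to force as IM-H.
#' @return data.frame: sample, cluster, immune_score, label.
#' @export
label_subtypes <- function(clusters, immune_scores, override = NULL) {
  if (length(unique(clusters)) != 2) {
    stop("label_subtypes: exactly two clusters required", call. = FALSE)
  }
  means <- tapply(immune_scores, clusters, mean)
  imh_cluster <- if (!is.null(override)) {
    override
  } else if (means[1] == means[2]) {
    stop("label_subtypes: cluster immune-score means are exactly equal; ",
         "supply `override` to break the tie", call. = FALSE)
  } else {
    as.integer(names(means)[which.max(means)])
  }
  data.frame(sample = if (!is.null(names(clusters))) names(clusters) else
               seq_along(clusters),
             cluster = as.integer(clusters),
             immune_score = as.numeric(immune_scores),
             label = ifelse(clusters == imh_cluster, "IM-H", "IM-L"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Discovery-cohort centroids for projection
#'
#' Per-gene mean normalized expression of each subtype over a gene panel
#' (typically the SAM-significant genes).
#'
#' @param logcpm normalized matrix.
#' @param labels "IM-H"/"IM-L" per sample.
#' @param panel_genes character vector of panel gene ids.
#' @return matrix, panel genes x c("IM-H", "IM-L").
#' @export
subtype_centroids <- function(logcpm, labels, panel_genes) {
  panel <- intersect(panel_genes, rownames(logcpm))
  m <- logcpm[panel, , drop = FALSE]
  cbind(`IM-H` = rowMeans(m[, labels == "IM-H", drop = FALSE]),
        `IM-L` = rowMeans(m[, labels == "IM-L", drop = FALSE]))
}

#' Project subtypes onto an external cohort
#'
#' Nearest-centroid classification with a margin: each external sample is
#' rank-correlated (Spearman) with both discovery centroids over the shared
#' panel genes; it takes the nearest centroid's label when the correlation
#' gap is at least `margin_threshold` and the best correlation is positive,
#' and is otherwise unassigned.
#'
#' @param external_matrix normalized matrix of the external cohort.
#' @param discovery_centroids matrix from [subtype_centroids()].
#' @param margin_threshold minimum correlation gap (default 0.1).
#' @return data.frame: sample, cor_imh, cor_iml, label ("IM-H", "IM-L" or
#'   "unassigned").
#' @export
project_subtypes <- function(external_matrix, discovery_centroids,
                             margin_threshold = 0.1) {
  shared <- intersect(rownames(discovery_centroids),
                      rownames(external_matrix))
  if (length(shared) < 20) {
    stop("project_subtypes: fewer than 20 shared panel genes (",
         length(shared), ")", call. = FALSE)
  }
  cen <- discovery_centroids[shared, , drop = FALSE]
  ext <- external_matrix[shared, , drop = FALSE]
  res <- t(vapply(seq_len(ncol(ext)), function(j) {
    c(stats::cor(ext[, j], cen[, "IM-H"], method = "spearman"),
      stats::cor(ext[, j], cen[, "IM-L"], method = "spearman"))
  }, numeric(2)))
  label <- rep("unassigned", nrow(res))
  gap <- abs(res[, 1] - res[, 2])
  best <- pmax(res[, 1], res[, 2])
  assign <- gap >= margin_threshold & best > 0
  label[assign & res[, 1] > res[, 2]] <- "IM-H"
  label[assign & res[, 2] > res[, 1]] <- "IM-L"
  data.frame(sample = colnames(ext), cor_imh = res[, 1], cor_iml = res[, 2],
             label = label, row.names = NULL, stringsAsFactors = FALSE)
}

#' Full transcriptomic subtyping stage
#'
#' TMM-normalizes counts, restricts to the most variable genes, runs
#' consensus NMF with rank diagnostics, clusters at rank 2 (the study's
#' two-subtype system), labels IM-H/IM-L by immune score, ranks genes with
#' SAM and builds projection centroids from the significant panel.
#'
#' @param counts raw count matrix, genes x samples.
#' @param immune_geneset,stromal_geneset character vectors.
#' @param ranks candidate NMF ranks.
#' @param n_restarts NMF restarts per rank.
#' @param n_top number of most-variable genes for NMF.
#' @param n_perm SAM permutations.
#' @param seed integer seed.
#' @return list with `normalization`, `nmf`, `chosen_rank`, `subtypes`
#'   (SubtypeResult data.frame incl. stromal score, purity proxy and
#'   silhouette width), `sam`, `centroids`.
#' @export
subtype_pipeline <- function(counts, immune_geneset, stromal_geneset,
                             ranks = 2:6, n_restarts = 30, n_top = 1500,
                             n_perm = 500, seed = 1L) {
  norm <- tmm_normalize(counts)
  feat <- nmf_feature_select(norm$logcpm, n_top = n_top)
  nmf <- nmf_consensus(feat, ranks = ranks, n_restarts = n_restarts,
                       seed = derive_seed(seed, "nmf"))
  two <- nmf$per_rank[["2"]]
  clusters <- two$clusters
  infil <- estimate_infiltration(norm$logcpm, immune_geneset,
                                 stromal_geneset)
  labelled <- label_subtypes(clusters, infil$immune_score)
  sil <- cluster::silhouette(clusters,
                             dmatrix = as.matrix(1 - two$consensus))
  subtypes <- data.frame(labelled,
                         stromal_score = infil$stromal_score,
                         purity_proxy = infil$purity_proxy,
                         silhouette = sil[, "sil_width"],
                         stringsAsFactors = FALSE)
  sam <- sam_rank(norm$logcpm, factor(labelled$label,
                                      levels = c("IM-L", "IM-H")),
                  n_perm = n_perm, seed = derive_seed(seed, "sam"))
  panel <- sam$gene[sam$significant]
  centroids <- if (length(panel) >= 2) {
    subtype_centroids(norm$logcpm, labelled$label, panel)
  } else {
    NULL
  }
  list(normalization = norm, nmf = nmf, chosen_rank = nmf$chosen_rank,
       subtypes = subtypes, sam = sam, centroids = centroids)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) {
    return(1)
  }
  (sij - expected) / (max_index - expected)
}
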