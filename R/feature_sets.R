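# Candidate feature-set construction: eight rule-built gene lists, each
# augmented with the mandatory cassette panel.

# order DE genes by FNAB adjusted p, breaking ties by larger |log2fc| and
# then lexicographic gene id (determinism)
rank_by_fnab <- function(de, genes) {
  fnab <- dplyr::filter(de, .data$context == "FNAB", .data$gene_id %in% genes)
  fnab$gene_id[order(fnab$adj_p, -abs(fnab$log2fc), fnab$gene_id)]
}

new_feature_set <- function(set_id, rule, genes, mandatory) {
  genes <- unique(c(genes, mandatory))
  tibble::tibble(set_id = as.integer(set_id), rule = rule, gene_id = genes,
                 mandatory = genes %in% mandatory)
}

# 1 - Pearson correlation distance between genes on log2(normalized + 1)
# over training FNAB samples
gene_distance <- function(x, genes) {
  train <- filter_samples(x, .data$cohort == "FNAB", .data$split == "train")
  sf <- size_factors(train)
  lx <- log2(sweep(train$counts[genes, , drop = FALSE], 2, sf, "/") + 1)
  cc <- suppressWarnings(cor(t(lx)))
  cc[!is.finite(cc)] <- 0 # zero-variance genes: treat as uncorrelated
  d <- 1 - cc
  diag(d) <- 0
  d
}

select_from_clusters <- function(de, clusters, frac = NULL, per_cluster_n = NULL) {
  unlist(lapply(split(names(clusters), clusters), function(genes) {
    k <- if (!is.null(per_cluster_n)) per_cluster_n else ceiling(frac * length(genes))
    head(rank_by_fnab(de, genes), k)
  }), use.names = FALSE)
}

#' Candidate feature sets 1 and 2: thresholded dual-context DE genes
#'
#' Set 1 keeps genes with dual-context adjusted p below `p_cut`; set 2
#' additionally requires a dual-context log2 fold change above `fc_cut`.
#' Both sets include the mandatory cassette genes unconditionally.
#'
#' @param de dual-context DE table from [de_table()].
#' @param mandatory character vector of mandatory gene ids.
#' @param p_cut adjusted-p threshold (default 1e-6).
#' @param fc_cut log2-fold-change floor for set 2 (default 6).
#' @return Tibble with columns `set_id`, `rule`, `gene_id`, `mandatory`.
#' @export
build_set_1_2 <- function(de, mandatory, p_cut = 1e-6, fc_cut = 6) {
  abort_if(nrow(de) == 0, "DE table is empty")
  dplyr::bind_rows(
    new_feature_set(1L, sprintf("dual-context adj_p < %g", p_cut),
                    dual_context_de(de, p_cut), mandatory),
    new_feature_set(2L, sprintf("dual-context adj_p < %g & log2FC > %g",
                                p_cut, fc_cut),
                    dual_context_de(de, p_cut, fc_cut), mandatory)
  )
}

#' Candidate feature sets 3-5: hierarchical clustering with per-cluster picks
#'
#' Dual-context DE genes at adjusted p below `p_cut` are clustered by
#' average-linkage hierarchical clustering on the 1 - Pearson-correlation
#' distance of log2(normalized count + 1) over training FNAB samples. The
#' tree is cut into `k = max(2, ceiling(sqrt(n_DE)))` clusters and from each
#' cluster the top 1, 20% or 50% genes (ceiling) by FNAB adjusted p are
#' selected, then unioned with the mandatory genes.
#'
#' @inheritParams build_set_1_2
#' @param x the [mtc_counts] the DE table was computed from.
#' @param p_cut adjusted-p threshold for the clustering filter (default 0.01).
#' @return Tibble of sets 3-5 in long form.
#' @export
build_sets_3_5 <- function(de, x, mandatory, p_cut = 0.01) {
  genes <- dual_context_de(de, p_cut)
  rules <- sprintf("hclust, %s per cluster", c("top 1", "top 20%", "top 50%"))
  if (length(genes) < 2) {
    warning("fewer than 2 dual-context DE genes; sets 3-5 are mandatory-only")
    return(dplyr::bind_rows(lapply(1:3, function(i) {
      new_feature_set(i + 2L, rules[i], character(0), mandatory)
    })))
  }
  d <- gene_distance(x, genes)
  hc <- hclust(as.dist(d), method = "average")
  k <- min(max(2L, ceiling(sqrt(length(genes)))), length(genes))
  cl <- cutree(hc, k = k)
  dplyr::bind_rows(
    new_feature_set(3L, rules[1],
                    select_from_clusters(de, cl, per_cluster_n = 1), mandatory),
    new_feature_set(4L, rules[2],
                    select_from_clusters(de, cl, frac = 0.2), mandatory),
    new_feature_set(5L, rules[3],
                    select_from_clusters(de, cl, frac = 0.5), mandatory)
  )
}

# recursive 2-medoid partitioning: a node is split when the candidate
# 2-cluster solution shows real structure (mean silhouette >= sil_cut),
# the node has >= min_size genes and the depth budget allows; leaves are
# the final clusters
recursive_medoid_partition <- function(d, sil_cut = 0.5, min_size = 10,
                                       max_depth = 4) {
  genes <- rownames(d)
  split_node <- function(idx, depth) {
    if (length(idx) < max(min_size, 3) || depth >= max_depth) return(list(idx))
    sub <- d[idx, idx, drop = FALSE]
    pm <- cluster::pam(as.dist(sub), k = 2, diss = TRUE)
    sil <- mean(cluster::silhouette(pm$clustering, as.dist(sub))[, "sil_width"])
    if (!is.finite(sil) || sil < sil_cut) return(list(idx))
    c(split_node(idx[pm$clustering == 1], depth + 1),
      split_node(idx[pm$clustering == 2], depth + 1))
  }
  leaves <- split_node(seq_along(genes), 0)
  cl <- integer(length(genes))
  for (i in seq_along(leaves)) cl[leaves[[i]]] <- i
  setNames(cl, genes)
}

#' Candidate feature sets 6-8: recursive partitioning with per-cluster picks
#'
#' Dual-context DE genes at adjusted p below `p_cut` are partitioned by a
#' recursive 2-medoid scheme on the same correlation distance as sets 3-5:
#' a gene set is split in two by partitioning around medoids whenever the
#' candidate split attains a mean silhouette width of at least 0.5, the set
#' holds at least 10 genes and the recursion is at most 4 deep; the leaves
#' are the final clusters. From each leaf the top 10%, 20% or 50% genes
#' (ceiling) by FNAB adjusted p are selected and unioned with the mandatory
#' genes.
#'
#' @inheritParams build_sets_3_5
#' @return Tibble of sets 6-8 in long form.
#' @export
build_sets_6_8 <- function(de, x, mandatory, p_cut = 0.01) {
  genes <- dual_context_de(de, p_cut)
  rules <- sprintf("recursive 2-medoid, top %s per cluster",
                   c("10%", "20%", "50%"))
  if (length(genes) < 2) {
    warning("fewer than 2 dual-context DE genes; sets 6-8 are mandatory-only")
    return(dplyr::bind_rows(lapply(1:3, function(i) {
      new_feature_set(i + 5L, rules[i], character(0), mandatory)
    })))
  }
  d <- gene_distance(x, genes)
  cl <- recursive_medoid_partition(d)
  dplyr::bind_rows(
    new_feature_set(6L, rules[1],
                    select_from_clusters(de, cl, frac = 0.1), mandatory),
    new_feature_set(7L, rules[2],
                    select_from_clusters(de, cl, frac = 0.2), mandatory),
    new_feature_set(8L, rules[3],
                    select_from_clusters(de, cl, frac = 0.5), mandatory)
  )
}

#' Build all eight candidate feature sets
#'
#' @inheritParams build_sets_3_5
#' @param p_strict adjusted-p threshold for sets 1-2 (default 1e-6).
#' @param fc_cut log2-fold-change floor for set 2 (default 6).
#' @param p_cluster adjusted-p threshold for the clustering sets (default
#'   0.01).
#' @return Tibble of class `mtc_feature_sets` (long form: `set_id`, `rule`,
#'   `gene_id`, `mandatory`).
#' @export
build_feature_sets <- function(de, x, mandatory, p_strict = 1e-6, fc_cut = 6,
                               p_cluster = 0.01) {
  out <- dplyr::bind_rows(
    build_set_1_2(de, mandatory, p_cut = p_strict, fc_cut = fc_cut),
    build_sets_3_5(de, x, mandatory, p_cut = p_cluster),
    build_sets_6_8(de, x, mandatory, p_cut = p_cluster)
  )
  class(out) <- c("mtc_feature_sets", class(out))
  out
}

#' Genes of one candidate feature set
#'
#' @param sets long-form feature-set tibble.
#' @param id set id in 1..8.
#' @return Character vector of gene ids.
#' @export
feature_set_genes <- function(sets, id) {
  g <- sets$gene_id[sets$set_id == id]
  abort_if(length(g) == 0, paste0("no feature set with id ", id))
  g
}
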