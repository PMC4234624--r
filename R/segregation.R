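#' Kullback-Leibler divergence of one group from the network distribution
#'
#' For a community with category counts \eqn{n_k(a)} and a network-wide
#' category distribution \eqn{p(a)},
#' \deqn{D_k = \sum_a p_k(a) \log_2 \frac{p_k(a)}{p(a)}}
#' with \eqn{p_k(a) = n_k(a)/n_k} and \eqn{0\log 0 = 0}. This is the
#' expected information gained about a member's category from knowing the
#' group, relative to drawing from the whole network.
#'
#' @param group_counts non-negative category counts for the group
#'   (aligned with \code{global_dist}).
#' @param global_dist network-wide category probabilities (sums to 1);
#'   must be positive on every category present in the group.
#' @return divergence in bits (>= 0).
#' @export
group_divergence <- function(group_counts, global_dist) {
  if (sum(group_counts) <= 0) stop("empty group", call. = FALSE)
  if (abs(sum(global_dist) - 1) > 1e-8) {
    stop("global_dist must sum to 1", call. = FALSE)
  }
  if (any(group_counts > 0 & global_dist <= 0)) {
    stop("group contains a category with zero global probability; inputs inconsistent",
         call. = FALSE)
  }
  pk <- group_counts / sum(group_counts)
  pos <- pk > 0
  sum(pk[pos] * log2(pk[pos] / global_dist[pos]))
}

## Fast path used by the permutation machinery: community and category as
## integer codes, group sizes precomputed. Returns the size-weighted total
## divergence S in bits.
seg_total_fast <- function(comm, cat, n_comm, n_cat) {
  n <- length(comm)
  counts <- tabulate((comm - 1L) * n_cat + cat, n_comm * n_cat)
  M <- matrix(counts, nrow = n_comm, ncol = n_cat, byrow = TRUE)
  nk <- rowSums(M)
  glob <- colSums(M) / n
  Pk <- M / nk
  ratio <- sweep(Pk, 2, glob, "/")
  pos <- M > 0
  contrib <- Pk[pos] * log2(ratio[pos])
  sum((nk / n)[row(M)[pos]] * contrib)
}

#' Total attribute segregation of a partition
#'
#' The size-weighted sum of the per-group divergences,
#' \deqn{S = \sum_k \frac{n_k}{n} D_k,}
#' with the network-wide distribution computed from the nodes present in
#' the partitioned network. \eqn{S} is 0 when every group matches the
#' global distribution and reaches the Shannon entropy of the global
#' distribution under perfect segregation (every group pure).
#'
#' @param partition named membership vector or \code{partition} object.
#' @param attrs an \code{attribute_table} covering the partitioned nodes.
#' @param attribute attribute name: "gender", "section" or "grade".
#' @return total segregation in bits.
#' @export
total_segregation <- function(partition, attrs, attribute) {
  pv <- partition_vector(partition)
  if (length(pv) == 0L) stop("empty partition", call. = FALSE)
  av <- node_categories(attrs, attribute, names(pv))
  comm <- as.integer(factor(pv, levels = unique(pv)))
  seg_total_fast(comm, as.integer(av), max(comm), nlevels(av))
}

node_categories <- function(attrs, attribute, nodes) {
  if (!attribute %in% c("gender", "section", "grade")) {
    stop("unknown attribute '", attribute, "'", call. = FALSE)
  }
  idx <- match(nodes, attrs$id)
  if (anyNA(idx)) {
    stop("node(s) missing from attribute table: ",
         paste(nodes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  droplevels(factor(attrs[[attribute]][idx]))
}

#' Maximum attainable segregation
#'
#' Under perfect segregation the total reduces to the Shannon entropy of
#' the network-wide category distribution, \eqn{S_{max} = -\sum_a p(a)
#' \log_2 p(a)}.
#'
#' @param global_dist category probabilities (sums to 1).
#' @return entropy in bits.
#' @export
max_segregation <- function(global_dist) {
  if (abs(sum(global_dist) - 1) > 1e-8) {
    stop("global_dist must sum to 1", call. = FALSE)
  }
  -sum(plogp(global_dist))
}

#' Permutation Z-score for attribute segregation
#'
#' The null model keeps the network structure and the partition fixed and
#' randomly re-distributes the attribute values over the partitioned
#' nodes (preserving the multiset of values). The Z-score standardizes
#' the observed statistic against \code{m_perms} such re-distributions:
#' \eqn{Z = (S_{obs} - \bar S_{null}) / sd(S_{null})}. With
#' \code{level = "per_group"} the same null yields a Z-score per
#' community from its divergence \eqn{D_k}.
#'
#' @param partition named membership vector or \code{partition} object.
#' @param attrs an \code{attribute_table}.
#' @param attribute attribute name.
#' @param m_perms number of permutations (>= 2).
#' @param seed integer seed.
#' @param level "network" for the total S, "per_group" for per-community
#'   divergences as well.
#' @param z_threshold two-sided significance threshold on |Z|.
#' @return list of class \code{segregation_result}: \code{attribute},
#'   \code{S}, \code{S_max}, \code{Z}, \code{significant},
#'   \code{null_mean}, \code{null_sd}, \code{m_perms}, \code{seed}, and
#'   (per_group level) \code{groups}, a data frame with community id,
#'   size, category counts, \code{D_k}, \code{Z_k} and significance
#'   flags. A constant attribute has zero null variance; its Z is NA with
#'   a warning.
#' @export
segregation_zscore <- function(partition, attrs, attribute, m_perms = 1000L,
                               seed = 1L, level = c("network", "per_group"),
                               z_threshold = 1.96) {
  level <- match.arg(level)
  stopifnot(m_perms >= 2L)
  pv <- partition_vector(partition)
  if (length(pv) == 0L) stop("empty partition", call. = FALSE)
  av <- node_categories(attrs, attribute, names(pv))
  comm <- as.integer(factor(pv, levels = unique(pv)))
  cat_i <- as.integer(av)
  n_comm <- max(comm); n_cat <- nlevels(av)
  n <- length(comm)
  glob <- tabulate(cat_i, n_cat) / n
  S_obs <- seg_total_fast(comm, cat_i, n_comm, n_cat)
  per_group <- level == "per_group"
  if (per_group) {
    D_obs <- group_divs(comm, cat_i, n_comm, n_cat, glob)
    D_null <- matrix(NA_real_, m_perms, n_comm)
  }
  set.seed(seed)
  S_null <- numeric(m_perms)
  for (b in seq_len(m_perms)) {
    shuf <- cat_i[sample.int(n)]
    S_null[b] <- seg_total_fast(comm, shuf, n_comm, n_cat)
    if (per_group) D_null[b, ] <- group_divs(comm, shuf, n_comm, n_cat, glob)
  }
  sd0 <- stats::sd(S_null)
  if (sd0 == 0) {
    warning("null distribution has zero variance (constant attribute?); Z undefined",
            call. = FALSE)
    Z <- NA_real_
  } else {
    Z <- (S_obs - mean(S_null)) / sd0
  }
  out <- list(attribute = attribute,
              S = S_obs,
              S_max = max_segregation(glob),
              Z = Z,
              significant = !is.na(Z) && abs(Z) > z_threshold,
              null_mean = mean(S_null), null_sd = sd0,
              m_perms = as.integer(m_perms), seed = as.integer(seed),
              z_threshold = z_threshold)
  if (per_group) {
    gsd <- apply(D_null, 2, stats::sd)
    Zk <- ifelse(gsd > 0, (D_obs - colMeans(D_null)) / gsd, NA_real_)
    sizes <- tabulate(comm, n_comm)
    out$groups <- data.frame(community = sort(unique(pv)),
                             size = sizes,
                             D_k = D_obs,
                             Z_k = Zk,
                             significant = !is.na(Zk) & abs(Zk) > z_threshold,
                             row.names = NULL)
  }
  structure(out, class = "segregation_result")
}

group_divs <- function(comm, cat, n_comm, n_cat, glob) {
  counts <- tabulate((comm - 1L) * n_cat + cat, n_comm * n_cat)
  M <- matrix(counts, nrow = n_comm, ncol = n_cat, byrow = TRUE)
  nk <- rowSums(M)
  Pk <- M / nk
  term <- Pk * log2(sweep(Pk, 2, glob, "/"))
  term[Pk == 0] <- 0
  rowSums(term)
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("segregation of '%s': S = %.4f bits (max %.4f), Z = %s [%s]\n",
              x$attribute, x$S, x$S_max,
              ifelse(is.na(x$Z), "NA", sprintf("%.2f", x$Z)),
              if (isTRUE(x$significant)) "significant" else "n.s."))
  if (!is.null(x$groups)) {
    cat(sprintf("  %d groups, %d significantly segregated\n",
                nrow(x$groups), sum(x$groups$significant, na.rm = TRUE)))
  }
  invisible(x)
}

#' Weekly segregation Z-scores for several attributes
#'
#' For each week, computes the network-level segregation Z-score of every
#' requested attribute against the permutation null, using the nodes
#' present in that week's partitioned network.
#'
#' @param networks ordered list of weekly networks.
#' @param partitions list of partitions aligned with \code{networks}.
#' @param attrs an \code{attribute_table}.
#' @param attributes attribute names to evaluate.
#' @param m_perms permutations per test.
#' @param seed integer seed.
#' @param z_threshold two-sided significance threshold.
#' @return data frame with columns \code{week}, \code{attribute},
#'   \code{S}, \code{S_max}, \code{Z}, \code{significant}.
#' @export
weekly_zscore_series <- function(networks, partitions, attrs,
                                 attributes = c("gender", "section", "grade"),
                                 m_perms = 1000L, seed = 1L,
                                 z_threshold = 1.96) {
  if (length(networks) != length(partitions)) {
    stop("networks and partitions must be aligned", call. = FALSE)
  }
  rows <- list()
  for (t in seq_along(networks)) {
    for (a in attributes) {
      r <- segregation_zscore(partitions[[t]], attrs, a, m_perms = m_perms,
                              seed = seed + t, z_threshold = z_threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(week = week_label(networks[[t]]), attribute = a,
                   S = r$S, S_max = r$S_max, Z = r$Z,
                   significant = r$significant,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
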