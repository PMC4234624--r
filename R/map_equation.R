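## Two-level map equation on directed networks.
##
## The random walker follows a uniformly chosen out-link with probability
## 1 - tau and teleports to a uniformly chosen node with probability tau
## (always, from a node without out-links). By default teleportation is
## "unrecorded": it only shapes the stationary visit rates, while module
## exit rates count link-following flow alone. With
## teleport_exit = "recorded", teleportation jumps that land outside the
## module are charged to the exit rate as well. Under both accountings a
## one-module partition has exit rate exactly 0 and its description length
## reduces to the entropy of the visit rates.

plogp <- function(x) {
  y <- numeric(length(x))
  pos <- x > 0
  y[pos] <- x[pos] * log2(x[pos])
  y
}

#' Stationary visit rates of a teleporting random walk
#'
#' Computes the stationary distribution of the walk by power iteration:
#' with probability \code{1 - tau} the walker follows a uniformly chosen
#' out-link of the current node, and with probability \code{tau} (or with
#' probability 1 from a node with no out-links) it teleports to a node
#' chosen uniformly among all nodes.
#'
#' @param net a directed network (igraph).
#' @param tau teleportation rate, in (0, 1).
#' @param tol convergence tolerance on the max-norm change per sweep.
#' @param max_iter iteration cap; exceeding it is an error with the last
#'   residual in the message.
#' @return list of class \code{visit_distribution} with \code{p} (named
#'   visit rates summing to 1), \code{tau}, \code{tol}, \code{iterations}.
#' @export
visit_frequencies <- function(net, tau = 0.15, tol = 1e-12, max_iter = 10000L) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)", call. = FALSE)
  el <- igraph::as_edgelist(net, names = FALSE)
  outdeg <- igraph::degree(net, mode = "out")
  dangling <- outdeg == 0
  p <- rep(1 / n, n)
  it <- 0L
  repeat {
    it <- it + 1L
    s_d <- sum(p[dangling])
    uniform <- (tau * (1 - s_d) + s_d) / n
    pnew <- rep(uniform, n)
    if (nrow(el)) {
      contrib <- (1 - tau) * p[el[, 1]] / outdeg[el[, 1]]
      agg <- rowsum(contrib, el[, 2])
      idx <- as.integer(rownames(agg))
      pnew[idx] <- pnew[idx] + agg[, 1]
    }
    delta <- max(abs(pnew - p))
    p <- pnew
    if (delta < tol) break
    if (it >= max_iter) {
      stop(sprintf("visit rates did not converge in %d iterations (residual %.3e, tol %.3e)",
                   max_iter, delta, tol), call. = FALSE)
    }
  }
  p <- p / sum(p)
  names(p) <- igraph::V(net)$name
  structure(list(p = p, tau = tau, tol = tol, iterations = it),
            class = "visit_distribution")
}

## Precompute everything the map-equation machinery needs:
## visit rates p, per-node teleport probability tt (tau, or 1 when
## dangling), and the sparse (link-following) flow lists
## F_ij = p_i (1 - tau) / outdeg_i.
me_prepare <- function(net, tau = 0.15, p = NULL, record = FALSE) {
  n <- igraph::vcount(net)
  if (is.null(p)) p <- visit_frequencies(net, tau = tau)$p
  pv <- if (is.null(names(p))) unname(p) else unname(p[igraph::V(net)$name])
  el <- igraph::as_edgelist(net, names = FALSE)
  outdeg <- igraph::degree(net, mode = "out")
  tt <- ifelse(outdeg == 0, 1, tau)
  fout_idx <- rep(list(integer(0)), n)
  fout_w <- rep(list(numeric(0)), n)
  fin_idx <- rep(list(integer(0)), n)
  fin_w <- rep(list(numeric(0)), n)
  if (nrow(el)) {
    w <- pv[el[, 1]] * (1 - tau) / outdeg[el[, 1]]
    fo <- split(seq_len(nrow(el)), el[, 1])
    for (s in names(fo)) {
      i <- as.integer(s)
      fout_idx[[i]] <- el[fo[[s]], 2]
      fout_w[[i]] <- w[fo[[s]]]
    }
    fi <- split(seq_len(nrow(el)), el[, 2])
    for (s in names(fi)) {
      j <- as.integer(s)
      fin_idx[[j]] <- el[fi[[s]], 1]
      fin_w[[j]] <- w[fi[[s]]]
    }
  }
  list(n = n, names = igraph::V(net)$name, p = pv, tt = tt, tau = tau,
       rec = if (record) 1 else 0,
       fout_idx = fout_idx, fout_w = fout_w,
       fin_idx = fin_idx, fin_w = fin_w,
       plogp_p = sum(plogp(pv)))
}

## Module statistics for a membership vector over the original nodes.
## Returns per-module node count, visit mass, teleport mass and sparse
## exit flow, from which exit rates follow in closed form.
me_module_stats <- function(prep, membership) {
  m <- max(membership)
  cnt <- tabulate(membership, m)
  sp <- as.vector(rowsum(prep$p, membership, reorder = TRUE))
  spt <- as.vector(rowsum(prep$p * prep$tt, membership, reorder = TRUE))
  wout <- numeric(m)
  for (i in seq_len(prep$n)) {
    tgt <- prep$fout_idx[[i]]
    if (length(tgt)) {
      ext <- membership[tgt] != membership[i]
      if (any(ext)) wout[membership[i]] <- wout[membership[i]] + sum(prep$fout_w[[i]][ext])
    }
  }
  list(cnt = cnt, sp = sp, spt = spt, wout = wout)
}

me_exit_rates <- function(prep, stats) {
  prep$rec * stats$spt * (prep$n - stats$cnt) / prep$n + stats$wout
}

## Expanded two-level map equation:
##   L = plogp(q) - 2 sum_k plogp(q_k) + sum_k plogp(q_k + sp_k) - sum_i plogp(p_i)
me_codelength <- function(prep, stats) {
  q_k <- me_exit_rates(prep, stats)
  q <- sum(q_k)
  plogp(q) - 2 * sum(plogp(q_k)) + sum(plogp(q_k + stats$sp)) - prep$plogp_p
}

#' Map-equation description length of a partition
#'
#' Evaluates the two-level map equation
#' \deqn{L(M) = q H(Q) + \sum_k p^{\circlearrowright}_k H(P_k)}
#' where \eqn{q_k} is the rate at which the walker exits module \eqn{k}
#' (link-following flow to other modules plus teleportation flow to nodes
#' outside the module), \eqn{q = \sum_k q_k}, \eqn{H(Q)} the entropy of
#' the normalized exit rates, \eqn{p^{\circlearrowright}_k = q_k +
#' \sum_{i \in k} p_i} the rate at which module \eqn{k}'s codebook is
#' used, and \eqn{H(P_k)} the entropy of the module's normalized node
#' visit and exit rates. All logarithms are base 2 (bits per step). With
#' a single module the index codebook is never used and \eqn{L} equals
#' the entropy of the visit rates.
#'
#' @param net directed network.
#' @param partition named membership vector (node -> community id) or a
#'   \code{partition} object; must cover the network's nodes.
#' @param p optional \code{visit_distribution} (recomputed when NULL).
#' @param tau teleportation rate.
#' @param teleport_exit \code{"unrecorded"} (default): exit rates count
#'   link-following flow only, teleportation only shapes the visit rates;
#'   \code{"recorded"}: teleportation jumps leaving the module are charged
#'   to the exit rate too.
#' @return list of class \code{codelength_report}: \code{total} (bits per
#'   step), \code{index_term}, \code{module_terms}, \code{q},
#'   \code{q_modules}, \code{n_modules}.
#' @export
description_length <- function(net, partition, p = NULL, tau = 0.15,
                               teleport_exit = c("unrecorded", "recorded")) {
  teleport_exit <- match.arg(teleport_exit)
  memb <- as_membership(partition, net)
  if (!is.null(p) && inherits(p, "visit_distribution")) p <- p$p
  prep <- me_prepare(net, tau = tau, p = p,
                     record = teleport_exit == "recorded")
  stats <- me_module_stats(prep, memb)
  q_k <- me_exit_rates(prep, stats)
  q <- sum(q_k)
  index_term <- if (q > 0) q * (-sum(plogp(q_k / q))) else 0
  pc <- q_k + stats$sp
  module_terms <- vapply(seq_along(q_k), function(k) {
    inside <- prep$p[memb == k]
    probs <- c(q_k[k], inside) / pc[k]
    pc[k] * (-sum(plogp(probs)))
  }, numeric(1))
  structure(list(total = index_term + sum(module_terms),
                 index_term = index_term,
                 module_terms = module_terms,
                 q = q, q_modules = q_k,
                 n_modules = length(q_k)),
            class = "codelength_report")
}

#' @export
print.codelength_report <- function(x, ...) {
  cat(sprintf("map-equation code length: %.6f bits/step over %d module(s)\n",
              x$total, x$n_modules))
  cat(sprintf("  index codebook: %.6f bits; total exit rate q = %.6f\n",
              x$index_term, x$q))
  invisible(x)
}

## Coerce a partition-like object (named vector, partition object, or plain
## vector aligned to V(net)) to an integer membership vector 1..m in the
## vertex order of net.
as_membership <- function(partition, net) {
  if (inherits(partition, "partition")) partition <- partition$membership
  nodes <- igraph::V(net)$name
  if (!is.null(names(partition))) {
    if (!all(nodes %in% names(partition))) {
      stop("partition does not cover all network nodes", call. = FALSE)
    }
    partition <- partition[nodes]
  } else if (length(partition) != length(nodes)) {
    stop("unnamed partition must have one entry per vertex", call. = FALSE)
  }
  as.integer(factor(partition, levels = unique(partition)))
}

#' Canonical community labels
#'
#' Relabels communities 1..m by decreasing size, breaking ties by the
#' smallest contained node id, giving a unique representative for each
#' partition of a labelled node set.
#'
#' @param membership named vector (node -> community id).
#' @return named integer vector with canonical labels.
#' @export
canonical_labels <- function(membership) {
  stopifnot(!is.null(names(membership)))
  f <- factor(membership, levels = unique(membership))
  sizes <- tabulate(f)
  first_node <- vapply(levels(f), function(l) min(names(membership)[f == l]), character(1))
  ord <- order(-sizes, first_node)
  new_id <- integer(nlevels(f))
  new_id[ord] <- seq_len(nlevels(f))
  out <- new_id[as.integer(f)]
  names(out) <- names(membership)
  out
}

## One greedy sweep stage at some aggregation level.
## Units carry (cnt, sp, spt) plus sparse inter-unit flows; membership maps
## units to modules. Moves a unit to the neighbouring (or an empty) module
## whenever the code length strictly decreases. Returns updated membership
## and whether anything moved.
me_sweep_units <- function(prep, units, membership, max_pass = 60L) {
  nu <- length(units$cnt)
  n <- prep$n
  ## module stats (indexed by module id; ids may have holes after moves)
  m_ids <- sort(unique(membership))
  mcnt <- msp <- mspt <- mwout <- numeric(max(membership) + nu)
  for (k in m_ids) {
    sel <- membership == k
    mcnt[k] <- sum(units$cnt[sel]); msp[k] <- sum(units$sp[sel])
    mspt[k] <- sum(units$spt[sel])
  }
  for (u in seq_len(nu)) {
    tgt <- units$fout_idx[[u]]
    if (length(tgt)) {
      ext <- membership[tgt] != membership[u]
      if (any(ext)) {
        mwout[membership[u]] <- mwout[membership[u]] + sum(units$fout_w[[u]][ext])
      }
    }
  }
  rec <- prep$rec
  qfun <- function(k) rec * mspt[k] * (n - mcnt[k]) / n + mwout[k]
  q_tot <- sum(vapply(which(mcnt > 0), qfun, numeric(1)))
  moved_any <- FALSE
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (u in sample.int(nu)) {
      a <- membership[u]
      ## flows between unit u and each module
      ot <- units$fout_idx[[u]]; ow <- units$fout_w[[u]]
      it <- units$fin_idx[[u]];  iw <- units$fin_w[[u]]
      fo_tot <- sum(ow)
      fo <- if (length(ot)) rowsum(ow, membership[ot]) else NULL
      fi <- if (length(it)) rowsum(iw, membership[it]) else NULL
      fo_ids <- if (is.null(fo)) integer(0) else as.integer(rownames(fo))
      fi_ids <- if (is.null(fi)) integer(0) else as.integer(rownames(fi))
      getf <- function(tab, ids, k) { j <- match(k, ids); if (is.na(j)) 0 else tab[j, 1] }
      cand <- setdiff(unique(c(fo_ids, fi_ids)), a)
      if (mcnt[a] > units$cnt[u]) {
        free <- which(mcnt == 0)[1]
        if (is.na(free)) { # extend arrays
          mcnt <- c(mcnt, 0); msp <- c(msp, 0); mspt <- c(mspt, 0); mwout <- c(mwout, 0)
          free <- length(mcnt)
        }
        cand <- c(cand, free)
      }
      if (!length(cand)) next
      qa <- qfun(a); pca <- qa + msp[a]
      fo_a <- getf(fo, fo_ids, a); fi_a <- getf(fi, fi_ids, a)
      ## module a without u
      a_cnt <- mcnt[a] - units$cnt[u]; a_sp <- msp[a] - units$sp[u]
      a_spt <- mspt[a] - units$spt[u]
      a_wout <- mwout[a] - (fo_tot - fo_a) + fi_a
      qa_new <- rec * a_spt * (n - a_cnt) / n + a_wout
      best_delta <- -1e-13; best_b <- NA_integer_
      best <- NULL
      for (b in cand) {
        qb <- qfun(b); pcb <- qb + msp[b]
        fo_b <- getf(fo, fo_ids, b); fi_b <- getf(fi, fi_ids, b)
        b_cnt <- mcnt[b] + units$cnt[u]; b_sp <- msp[b] + units$sp[u]
        b_spt <- mspt[b] + units$spt[u]
        b_wout <- mwout[b] + (fo_tot - fo_b) - fi_b
        qb_new <- rec * b_spt * (n - b_cnt) / n + b_wout
        q_new <- q_tot - qa - qb + qa_new + qb_new
        delta <- (plogp(q_new) - plogp(q_tot)) -
          2 * (plogp(qa_new) + plogp(qb_new) - plogp(qa) - plogp(qb)) +
          (plogp(qa_new + a_sp) + plogp(qb_new + b_sp) -
             plogp(pca) - plogp(qb + msp[b]))
        if (delta < best_delta) {
          best_delta <- delta; best_b <- b
          best <- list(qb_new = qb_new, b_cnt = b_cnt, b_sp = b_sp,
                       b_spt = b_spt, b_wout = b_wout, q_new = q_new)
        }
      }
      if (!is.na(best_b)) {
        b <- best_b
        q_tot <- best$q_new
        mcnt[a] <- a_cnt; msp[a] <- a_sp; mspt[a] <- a_spt; mwout[a] <- a_wout
        mcnt[b] <- best$b_cnt; msp[b] <- best$b_sp
        mspt[b] <- best$b_spt; mwout[b] <- best$b_wout
        membership[u] <- b
        moved <- TRUE; moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = membership, moved = moved_any)
}

## Build node-level units from a prepared network.
me_node_units <- function(prep) {
  list(cnt = rep(1L, prep$n), sp = prep$p, spt = prep$p * prep$tt,
       fout_idx = prep$fout_idx, fout_w = prep$fout_w,
       fin_idx = prep$fin_idx, fin_w = prep$fin_w)
}

## Aggregate node membership into module-level units (intra-module flows
## dropped; they never cross a module boundary at the coarser level).
me_aggregate_units <- function(prep, membership) {
  ids <- sort(unique(membership))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  memb <- remap[membership]
  m <- length(ids)
  cnt <- tabulate(memb, m)
  sp <- as.vector(rowsum(prep$p, memb, reorder = TRUE))
  spt <- as.vector(rowsum(prep$p * prep$tt, memb, reorder = TRUE))
  src <- integer(0); dst <- integer(0); w <- numeric(0)
  for (i in seq_len(prep$n)) {
    tgt <- prep$fout_idx[[i]]
    if (length(tgt)) {
      src <- c(src, rep.int(memb[i], length(tgt)))
      dst <- c(dst, memb[tgt])
      w <- c(w, prep$fout_w[[i]])
    }
  }
  keep <- src != dst
  src <- src[keep]; dst <- dst[keep]; w <- w[keep]
  fout_idx <- rep(list(integer(0)), m); fout_w <- rep(list(numeric(0)), m)
  fin_idx <- rep(list(integer(0)), m); fin_w <- rep(list(numeric(0)), m)
  if (length(src)) {
    key <- paste(src, dst)
    agg <- rowsum(w, key)
    parts <- strsplit(rownames(agg), " ", fixed = TRUE)
    s2 <- vapply(parts, function(x) as.integer(x[1]), integer(1))
    d2 <- vapply(parts, function(x) as.integer(x[2]), integer(1))
    w2 <- agg[, 1]
    for (k in seq_len(m)) {
      sel <- s2 == k
      fout_idx[[k]] <- d2[sel]; fout_w[[k]] <- w2[sel]
      sel <- d2 == k
      fin_idx[[k]] <- s2[sel]; fin_w[[k]] <- w2[sel]
    }
  }
  list(units = list(cnt = cnt, sp = sp, spt = spt,
                    fout_idx = fout_idx, fout_w = fout_w,
                    fin_idx = fin_idx, fin_w = fin_w),
       memb = memb)
}

## One full greedy run: node-level sweeps alternating with module-level
## (aggregated) sweeps until the code length stops improving.
me_one_run <- function(prep) {
  units <- me_node_units(prep)
  membership <- seq_len(prep$n)
  repeat {
    res <- me_sweep_units(prep, units, membership)
    membership <- res$membership
    agg <- me_aggregate_units(prep, membership)
    if (length(agg$units$cnt) <= 1L) break
    sup <- me_sweep_units(prep, agg$units, seq_along(agg$units$cnt))
    if (!res$moved && !sup$moved) break
    membership <- sup$membership[agg$memb]
  }
  ## compact ids
  as.integer(factor(membership, levels = unique(membership)))
}

#' Detect communities by minimizing the map equation
#'
#' Greedy two-level search: each run starts from singleton modules and
#' alternates node-level moves with aggregated module-level moves, in
#' randomized visit order, while the description length decreases. The
#' best of \code{n_runs} runs (minimal code length, ties broken by the
#' lexicographically smallest canonical labelling) is returned.
#' Deterministic given \code{seed}.
#'
#' @param net directed network.
#' @param tau teleportation rate.
#' @param n_runs number of independent greedy runs.
#' @param seed integer seed.
#' @param p optional precomputed \code{visit_distribution}.
#' @param teleport_exit exit-rate accounting, see [description_length()].
#' @return list of class \code{partition}: \code{membership} (named,
#'   canonical labels), \code{codelength} (a \code{codelength_report}),
#'   \code{sizes}, \code{n_modules}, \code{tau}, \code{n_runs},
#'   \code{seed}.
#' @export
detect_communities <- function(net, tau = 0.15, n_runs = 100L, seed = 1L,
                               p = NULL,
                               teleport_exit = c("unrecorded", "recorded")) {
  teleport_exit <- match.arg(teleport_exit)
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  if (!is.null(p) && inherits(p, "visit_distribution")) p <- p$p
  prep <- me_prepare(net, tau = tau, p = p,
                     record = teleport_exit == "recorded")
  set.seed(seed)
  best_L <- Inf; best_memb <- NULL
  for (r in seq_len(n_runs)) {
    memb <- me_one_run(prep)
    L <- me_codelength(prep, me_module_stats(prep, memb))
    named <- memb; names(named) <- prep$names
    canon <- canonical_labels(named)
    if (L < best_L - 1e-12 ||
        (abs(L - best_L) <= 1e-12 && !is.null(best_memb) &&
         lex_less(canon, best_memb))) {
      best_L <- L
      best_memb <- canon
    }
  }
  report <- description_length(net, best_memb, p = prep$p, tau = tau,
                               teleport_exit = teleport_exit)
  structure(list(membership = best_memb,
                 codelength = report,
                 sizes = as.integer(table(best_memb)),
                 n_modules = max(best_memb),
                 tau = tau, n_runs = n_runs, seed = seed),
            class = "partition")
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes in %d communities (L = %.4f bits/step)\n",
              length(x$membership), x$n_modules, x$codelength$total))
  cat("sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' Directed modularity of a partition
#'
#' \deqn{Q = \frac{1}{E}\sum_{ij}\left[A_{ij} - \frac{k^{out}_i k^{in}_j}{E}\right]\delta(c_i, c_j)}
#' over the directed edges, where \eqn{E} is the edge count.
#'
#' @param net directed network (must have at least one edge).
#' @param partition membership vector or \code{partition} object.
#' @return modularity value.
#' @export
modularity_directed <- function(net, partition) {
  memb <- as_membership(partition, net)
  E <- igraph::ecount(net)
  if (E == 0L) stop("modularity undefined on a zero-edge network", call. = FALSE)
  el <- igraph::as_edgelist(net, names = FALSE)
  within <- sum(memb[el[, 1]] == memb[el[, 2]]) / E
  kout <- igraph::degree(net, mode = "out")
  kin <- igraph::degree(net, mode = "in")
  m <- max(memb)
  Kout <- as.vector(rowsum(kout, memb, reorder = TRUE))
  Kin <- as.vector(rowsum(kin, memb, reorder = TRUE))
  within - sum(Kout * Kin) / E^2
}

#' Between-run stability of the community detection
#'
#' Repeats detection \code{n_pairs + 1} times with different run seeds and
#' reports the mean and standard error of the variation of information
#' between consecutive runs, along with the mean number of communities,
#' mean modularity and mean description length — the usual robustness
#' summary for stochastic community detection.
#'
#' @param net directed network.
#' @param tau teleportation rate.
#' @param n_pairs number of consecutive-run pairs (>= 1).
#' @param n_runs_each greedy runs per detection.
#' @param seed integer seed.
#' @return list with \code{vi_mean}, \code{vi_se} (NA when
#'   \code{n_pairs} is 1), \code{m_mean}, \code{Q_mean}, \code{L_mean},
#'   \code{n_pairs}.
#' @export
run_stability <- function(net, tau = 0.15, n_pairs = 10L, n_runs_each = 1L,
                          seed = 1L) {
  stopifnot(n_pairs >= 1L)
  p <- visit_frequencies(net, tau = tau)
  dets <- lapply(seq_len(n_pairs + 1L), function(r) {
    detect_communities(net, tau = tau, n_runs = n_runs_each,
                       seed = seed + r, p = p)
  })
  vi <- vapply(seq_len(n_pairs), function(r) {
    variation_of_information(dets[[r]]$membership, dets[[r + 1L]]$membership)
  }, numeric(1))
  Q <- vapply(dets, function(d) modularity_directed(net, d), numeric(1))
  list(vi_mean = mean(vi),
       vi_se = if (n_pairs > 1L) stats::sd(vi) / sqrt(n_pairs) else NA_real_,
       m_mean = mean(vapply(dets, function(d) d$n_modules, numeric(1))),
       Q_mean = mean(Q),
       L_mean = mean(vapply(dets, function(d) d$codelength$total, numeric(1))),
       n_pairs = n_pairs)
}
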