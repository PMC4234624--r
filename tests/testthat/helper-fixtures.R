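# Shared fixtures and independent oracles for the test suite.

# Three toy weeks with known link-turnover arithmetic:
# W1 = {A->B, B->C}, W2 = {A->B, C->D}, W3 = {B->C, C->D, D->E}.
toy_weeks <- function() {
  list(weekly_network(data.frame(s = c("A", "B"), t = c("B", "C")), 1),
       weekly_network(data.frame(s = c("A", "C"), t = c("B", "D")), 2),
       weekly_network(data.frame(s = c("B", "C", "D"), t = c("C", "D", "E")), 3))
}

# Bidirected clique on the given ids (all ordered pairs).
bidirected_clique <- function(ids) {
  el <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  el <- el[el$s != el$t, ]
  weekly_network(el, 1)
}

# Two bidirected 4-cliques, optionally joined by a single arc n1 -> n5.
two_cliques <- function(joined = FALSE) {
  pairs <- function(ids) {
    el <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
    el[el$s != el$t, ]
  }
  el <- rbind(pairs(paste0("n", 1:4)), pairs(paste0("n", 5:8)))
  if (joined) el <- rbind(el, data.frame(s = "n1", t = "n5"))
  weekly_network(el, 1)
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  res <- list()
  rg <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      res[[length(res) + 1L]] <<- rg[seq_len(n)]
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) {
      rg[i] <<- v
      rec(i + 1L, max(mx, v))
    }
  }
  rec(1L, 0L)
  res
}

# Dense linear-solve oracle for the teleporting walk and the map equation,
# computed straight from the definitions (no shared code with the package
# internals).
dense_flow <- function(net, tau = 0.15) {
  n <- igraph::vcount(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  outdeg <- rowSums(A)
  tt <- ifelse(outdeg == 0, 1, tau)
  Tlink <- matrix(0, n, n)
  nz <- outdeg > 0
  Tlink[nz, ] <- (1 - tau) * A[nz, , drop = FALSE] / outdeg[nz]
  Tfull <- Tlink + tt %o% rep(1 / n, n)
  # stationary p: p = p Tfull, sum(p) = 1, via direct linear solve
  M <- t(diag(n) - Tfull)
  M[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- solve(M, b)
  list(p = p, Tlink = Tlink, Tfull = Tfull, tt = tt, n = n,
       names = igraph::V(net)$name)
}

# Map-equation value for a membership vector (aligned with vertex order),
# evaluated from the definition: L = q H(Q) + sum_k pc_k H(P_k).
oracle_codelength <- function(flow, memb, record = FALSE) {
  ent <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  m <- max(memb)
  p <- flow$p
  n <- flow$n
  q_k <- vapply(seq_len(m), function(k) {
    inside <- memb == k
    q_link <- sum(p[inside] * rowSums(flow$Tlink[inside, !inside, drop = FALSE]))
    if (record) {
      q_link + sum(p[inside] * flow$tt[inside]) * (n - sum(inside)) / n
    } else q_link
  }, numeric(1))
  q <- sum(q_k)
  idx <- if (q > 0) q * ent(q_k / q) else 0
  mod <- vapply(seq_len(m), function(k) {
    pc <- q_k[k] + sum(p[memb == k])
    pc * ent(c(q_k[k], p[memb == k]) / pc)
  }, numeric(1))
  idx + sum(mod)
}

# Direct double-sum directed modularity oracle.
oracle_modularity <- function(net, memb) {
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  E <- sum(A)
  kout <- rowSums(A)
  kin <- colSums(A)
  same <- outer(memb, memb, "==")
  sum((A - outer(kout, kin) / E) * same) / E
}

# Attribute table over given ids with supplied vectors (single-category
# section/grade defaults keep unrelated attributes inert).
make_attrs <- function(ids, gender = rep("M", length(ids)),
                       section = rep("1", length(ids)),
                       grade = rep("7", length(ids)),
                       vocab = NULL) {
  attribute_table(data.frame(id = ids, gender = gender, section = section,
                             grade = grade, stringsAsFactors = FALSE),
                  vocab = vocab)
}

# Random partition of a node set into at most k parts.
random_partition <- function(nodes, k) {
  setNames(sample.int(k, length(nodes), replace = TRUE), nodes)
}
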