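#' Link turnover across an ordered sequence of weekly networks
#'
#' For each week \eqn{t} the summary reports the total number of directed
#' links \eqn{E_{tot}(t)}; the number of new links \eqn{E_{new}(t)} absent
#' from the immediately preceding week; the number of re-established links
#' \eqn{E_{re}(t)} present in at least one earlier week; and the fraction
#' \eqn{f_{new}(t)} of links never seen in any earlier week. A link can be
#' new with respect to \eqn{t-1} yet re-established with respect to an
#' earlier week, so \eqn{E_{new}} and \eqn{E_{re}} need not partition
#' \eqn{E_{tot}}. For the first week \eqn{E_{new} = E_{tot}} and
#' \eqn{E_{re} = 0} by convention. Node count, active-namer count
#' (out-degree >= 1), density \eqn{E_{tot}/(N(N-1))} and directed diameter
#' are included per week.
#'
#' @param networks ordered list of weekly networks (chronological).
#' @return data frame with one row per week, columns \code{week},
#'   \code{E_tot}, \code{E_new}, \code{E_re}, \code{f_new},
#'   \code{n_nodes}, \code{n_active}, \code{density}, \code{diameter}.
#' @export
link_counts <- function(networks) {
  if (length(networks) == 0L) stop("need at least one network", call. = FALSE)
  keys <- lapply(networks, edge_keys)
  n_weeks <- length(networks)
  out <- data.frame(
    week = vapply(networks, week_label, integer(1)),
    E_tot = lengths(keys),
    E_new = NA_integer_, E_re = NA_integer_, f_new = NA_real_,
    n_nodes = vapply(networks, igraph::vcount, numeric(1)),
    n_active = vapply(networks, function(g) {
      sum(igraph::degree(g, mode = "out") >= 1)
    }, numeric(1)),
    density = NA_real_, diameter = NA_real_,
    row.names = NULL)
  seen <- character(0)
  for (t in seq_len(n_weeks)) {
    k <- keys[[t]]
    if (t == 1L) {
      out$E_new[t] <- length(k)
      out$E_re[t] <- 0L
      out$f_new[t] <- if (length(k)) 1 else NaN
    } else {
      out$E_new[t] <- length(setdiff(k, keys[[t - 1L]]))
      out$E_re[t] <- length(intersect(k, seen))
      out$f_new[t] <- if (length(k)) length(setdiff(k, seen)) / length(k) else NaN
    }
    seen <- union(seen, k)
    nn <- out$n_nodes[t]
    out$density[t] <- if (nn > 1) out$E_tot[t] / (nn * (nn - 1)) else NaN
    out$diameter[t] <- net_diameter(networks[[t]])
  }
  out
}

#' Number and fraction of unique directed links across all weeks
#'
#' Counts the distinct ordered pairs used in any week and expresses them
#' as a percentage of the \eqn{N(N-1)} possible directed links.
#'
#' @param networks ordered list of weekly networks.
#' @param n_nodes node-count convention: either a supplied \eqn{N} or
#'   (default) the size of the union of all weekly vertex sets.
#' @return list with \code{unique_links}, \code{n_nodes},
#'   \code{possible_links}, and \code{percent} (0-100 scale).
#' @export
unique_link_count <- function(networks, n_nodes = NULL) {
  keys <- unique(unlist(lapply(networks, edge_keys)))
  if (is.null(n_nodes)) {
    n_nodes <- length(unique(unlist(lapply(networks, function(g) igraph::V(g)$name))))
  }
  if (n_nodes < 2) stop("need at least two nodes", call. = FALSE)
  possible <- n_nodes * (n_nodes - 1)
  list(unique_links = length(keys), n_nodes = n_nodes,
       possible_links = possible, percent = 100 * length(keys) / possible)
}

#' Accumulated link-weight distribution
#'
#' The weight of an ordered pair after week \eqn{t} is the number of weeks
#' up to and including \eqn{t} in which the link occurred,
#' \eqn{w_{ij} = \sum_{s \le t} A_{ij}(s)}. The histogram shows how many
#' links have been used once, twice, and so on.
#'
#' @param networks ordered list of weekly networks.
#' @param upto_week week label (must be present) through which to
#'   accumulate; defaults to the last week.
#' @return list with \code{weights} (named integer vector over "src\\tdst"
#'   pairs) and \code{histogram} (data frame weight/count).
#' @export
link_weight_distribution <- function(networks, upto_week = NULL) {
  labs <- vapply(networks, week_label, integer(1))
  if (is.null(upto_week)) upto_week <- labs[length(labs)]
  if (!upto_week %in% labs) stop("upto_week not present in sequence", call. = FALSE)
  use <- networks[labs <= upto_week]
  all_keys <- unlist(lapply(use, edge_keys))
  if (length(all_keys) == 0L) {
    return(list(weights = integer(0),
                histogram = data.frame(weight = integer(0), count = integer(0))))
  }
  w <- table(all_keys)
  weights <- as.integer(w)
  names(weights) <- gsub("\r", "\t", names(w), fixed = TRUE)
  h <- table(weights)
  list(weights = weights,
       histogram = data.frame(weight = as.integer(names(h)),
                              count = as.integer(h), row.names = NULL))
}

#' Degree statistics and cumulative degree distribution
#'
#' The cumulative distribution is \eqn{P(k) = \sum_{k' \ge k} p_{k'}} over
#' the observed degree sequence, so \eqn{P(k_{min}) = 1}. The mean is the
#' first moment; the spread is the moment-based standard deviation
#' \eqn{\sqrt{\langle k^2\rangle - \langle k\rangle^2}}, reported together
#' with its standard error \eqn{sd/\sqrt{n}}.
#'
#' @param net a weekly network.
#' @param mode degree mode: "in", "out" or "total".
#' @return list with \code{degrees}, \code{cumulative} (data frame k,
#'   P_k), \code{mean}, \code{sd}, \code{sem}, \code{moments} (first and
#'   second raw moments).
#' @export
degree_stats <- function(net, mode = c("in", "out", "total")) {
  mode <- match.arg(mode)
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  deg <- igraph::degree(net, mode = if (mode == "total") "all" else mode)
  n <- length(deg)
  ks <- sort(unique(deg))
  pk <- vapply(ks, function(k) sum(deg == k) / n, numeric(1))
  cum <- rev(cumsum(rev(pk)))
  m1 <- mean(deg)
  m2 <- mean(deg^2)
  sdv <- sqrt(max(m2 - m1^2, 0))
  list(degrees = deg,
       cumulative = data.frame(k = ks, P_k = cum),
       mean = m1, sd = sdv, sem = sdv / sqrt(n),
       moments = c(m1 = m1, m2 = m2))
}

#' Directed diameter over reachable ordered pairs
#'
#' Longest shortest directed path among ordered pairs that are connected;
#' unreachable pairs are ignored, so on a weakly disconnected digraph this
#' is the maximum finite directed eccentricity. A network with no edges
#' has diameter 0.
#'
#' @param net a weekly network.
#' @return integer path length.
#' @export
net_diameter <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  if (igraph::ecount(net) == 0L) return(0)
  d <- igraph::distances(net, mode = "out")
  max(d[is.finite(d)])
}
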