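# Median-joining haplotype networks (Bandelt, Forster & Roehl 1999 scheme):
# an epsilon-relaxed minimum spanning network over Hamming distances is
# iteratively augmented with consensus (median) vectors of linked triplets
# when they shorten the network, then pruned so that every surviving median
# has degree >= 3.

hamming_matrix <- function(m) {
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(k - 1, 0))) {
    for (j in (i + 1):k) d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

# epsilon-relaxed minimum spanning network: repeatedly connect components by
# every cross-component link within epsilon of the cheapest one. Ties broken
# deterministically by (weight, lexicographic node names).
msn_edges <- function(d, epsilon = 0) {
  k <- nrow(d)
  comp <- seq_len(k)
  edges <- list()
  while (length(unique(comp)) > 1) {
    cross <- which(outer(comp, comp, "!=") & upper.tri(d), arr.ind = TRUE)
    w <- d[cross]
    dmin <- min(w)
    take <- which(w <= dmin + epsilon)
    take <- take[order(w[take], rownames(d)[cross[take, 1]],
                       rownames(d)[cross[take, 2]])]
    for (t in take) {
      i <- cross[t, 1]; j <- cross[t, 2]
      edges[[length(edges) + 1]] <- c(i, j, d[i, j])
    }
    # merge all components touched at this level
    for (t in take) {
      i <- cross[t, 1]; j <- cross[t, 2]
      old <- comp[j]
      comp[comp == old] <- comp[i]
    }
  }
  if (!length(edges)) {
    return(tibble(from = integer(0), to = integer(0), steps = integer(0)))
  }
  e <- do.call(rbind, edges)
  tibble(from = pmin(e[, 1], e[, 2]), to = pmax(e[, 1], e[, 2]),
         steps = e[, 3]) |> distinct()
}

consensus_median <- function(a, b, c) {
  out <- a
  for (s in seq_along(a)) {
    states <- c(a[s], b[s], c[s])
    tab <- table(states)
    if (max(tab) >= 2) {
      out[s] <- names(tab)[which.max(tab)]
    } else {
      out[s] <- min(states)   # all three distinct: deterministic tie-break
    }
  }
  out
}

#' Median-joining haplotype network
#'
#' @param ht A `haplotype_table` from [collapse_haplotypes()] (or an
#'   alignment tibble, collapsed internally). Monomorphic columns are dropped
#'   before network construction.
#' @param epsilon Relaxation parameter of the minimum spanning network
#'   (default 0, the Network v4.6 default).
#' @return Object of class `haplotype_network`: list with `graph` (igraph,
#'   edge attribute `steps`, vertex attributes `type` observed/median and
#'   `freq`), `nodes` and `edges` tibbles, and `epsilon`. Median vectors are
#'   labelled `MV1, MV2, ...` and carry frequency 0.
#' @export
mj_network <- function(ht, epsilon = 0) {
  if (is.data.frame(ht)) ht <- collapse_haplotypes(ht)
  stopifnot(inherits(ht, "haplotype_table"))
  seqs <- ht$haplotypes$sequence
  labels <- ht$haplotypes$haplotype
  if (length(seqs) < 2) abort("need >= 2 haplotypes")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- labels
  # restrict to variable columns among comparable sites
  keep <- intersect(which(apply(m, 2, function(col) length(unique(col)) > 1)),
                    which(apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))))
  m <- m[, keep, drop = FALSE]
  freq <- ht$haplotypes$n
  types <- rep("observed", nrow(m))
  mv_count <- 0

  total_len <- function(ed) sum(ed$steps)
  edges <- msn_edges(hamming_matrix(m), epsilon)
  for (iter in seq_len(25)) {
    d <- hamming_matrix(m)
    # feasible triples: two links sharing a node
    adj <- lapply(seq_len(nrow(m)), function(i) {
      c(edges$to[edges$from == i], edges$from[edges$to == i])
    })
    row_keys <- apply(m, 1, paste, collapse = "")
    cands <- list()
    for (u in seq_len(nrow(m))) {
      nb <- unique(adj[[u]])
      if (length(nb) < 2) next
      prs <- utils::combn(sort(nb), 2)
      for (pc in seq_len(ncol(prs))) {
        v <- prs[1, pc]; w <- prs[2, pc]
        med <- consensus_median(m[u, ], m[v, ], m[w, ])
        key <- paste(med, collapse = "")
        if (key %in% row_keys) next
        cost <- sum(med != m[u, ]) + sum(med != m[v, ]) + sum(med != m[w, ])
        cands[[key]] <- min(cost, cands[[key]] %||% Inf)
      }
    }
    if (!length(cands)) break
    lambda <- min(unlist(cands))
    new_keys <- names(cands)[unlist(cands) == lambda]
    m_new <- rbind(m, do.call(rbind, strsplit(new_keys, "")))
    mv_labels <- paste0("MV", mv_count + seq_along(new_keys))
    rownames(m_new) <- c(rownames(m), mv_labels)
    edges_new <- msn_edges(hamming_matrix(m_new), epsilon)
    if (total_len(edges_new) > total_len(edges)) break   # medians don't help
    m <- m_new
    freq <- c(freq, rep(0L, length(new_keys)))
    types <- c(types, rep("median", length(new_keys)))
    mv_count <- mv_count + length(new_keys)
    edges <- edges_new
  }

  # prune: medians must have degree >= 3 (a degree-2 median on a geodesic is
  # redundant; Hamming distance is metric so the direct link replaces it)
  repeat {
    deg <- tabulate(c(edges$from, edges$to), nbins = nrow(m))
    drop <- which(types == "median" & deg <= 2)
    if (!length(drop)) break
    keep_rows <- setdiff(seq_len(nrow(m)), drop)
    m <- m[keep_rows, , drop = FALSE]
    freq <- freq[keep_rows]
    types <- types[keep_rows]
    edges <- msn_edges(hamming_matrix(m), epsilon)
  }

  nodes <- tibble(name = rownames(m), type = types, freq = as.integer(freq))
  ed <- tibble(from = rownames(m)[edges$from], to = rownames(m)[edges$to],
               steps = as.integer(edges$steps))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = ed, epsilon = epsilon,
                 counts = ht$counts),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype_network> ", sum(x$nodes$type == "observed"),
      " observed haplotypes + ", sum(x$nodes$type == "median"),
      " median vectors, ", nrow(x$edges), " links (total length ",
      sum(x$edges$steps), ", epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' @export
glance.haplotype_network <- function(x, ...) {
  tibble(n_observed = sum(x$nodes$type == "observed"),
         n_median = sum(x$nodes$type == "median"),
         n_edges = nrow(x$edges),
         total_steps = sum(x$edges$steps),
         epsilon = x$epsilon)
}

#' @importFrom ggplot2 geom_segment geom_point geom_text theme_void
#' @export
autoplot.haplotype_network <- function(object, seed = 1L, ...) {
  lay <- with_seed(seed, igraph::layout_with_fr(object$graph,
                                                weights = igraph::E(object$graph)$steps))
  nd <- object$nodes |> mutate(x = lay[, 1], y = lay[, 2])
  ed <- object$edges |>
    left_join(nd |> select("name", x1 = "x", y1 = "y"), by = c(from = "name")) |>
    left_join(nd |> select("name", x2 = "x", y2 = "y"), by = c(to = "name"))
  ggplot() +
    geom_segment(data = ed, aes(x = .data$x1, y = .data$y1,
                                xend = .data$x2, yend = .data$y2),
                 colour = "grey50") +
    geom_point(data = nd, aes(x = .data$x, y = .data$y,
                              size = pmax(.data$freq, 0.5),
                              colour = .data$type)) +
    geom_text(data = nd[nd$type == "observed", ],
              aes(x = .data$x, y = .data$y, label = .data$name),
              vjust = -1, size = 3) +
    theme_void() +
    labs(size = "frequency", colour = NULL)
}

#' Partition observed haplotypes into haplogroups
#'
#' Observed haplotypes are clustered by single linkage on network path length
#' (sum of mutational steps along the shortest path): two haplotypes fall in
#' the same haplogroup when connected by a path shorter than `min_steps`.
#'
#' @param net A `haplotype_network`.
#' @param min_steps Minimum divergence (mutational steps) separating
#'   haplogroups.
#' @return List with `membership` (tibble haplotype/haplogroup), `bridges`
#'   (tibble of haplogroup pairs and the minimum inter-group path length) and
#'   `max_bridge` (the maximum of those minima; `NA` with one haplogroup).
#' @export
haplogroups <- function(net, min_steps) {
  stopifnot(min_steps >= 1)
  obs <- net$nodes$name[net$nodes$type == "observed"]
  dp <- igraph::distances(net$graph, v = obs, to = obs,
                          weights = igraph::E(net$graph)$steps)
  close <- dp < min_steps
  gg <- igraph::graph_from_adjacency_matrix(close, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gg)$membership
  membership <- tibble(haplotype = obs, haplogroup = paste0("G", comp))
  groups <- sort(unique(membership$haplogroup))
  bridges <- NULL
  if (length(groups) > 1) {
    res <- list()
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        gi <- membership$haplotype[membership$haplogroup == groups[i]]
        gj <- membership$haplotype[membership$haplogroup == groups[j]]
        res[[length(res) + 1]] <- tibble(
          group1 = groups[i], group2 = groups[j],
          bridge_steps = min(dp[gi, gj, drop = FALSE]))
      }
    }
    bridges <- bind_rows(res)
  }
  list(membership = membership, bridges = bridges,
       max_bridge = if (is.null(bridges)) NA_real_ else max(bridges$bridge_steps))
}

#' Minimum Hamming distance between the haplotypes of two groups
#'
#' Complements the network bridge length: the smallest raw pairwise distance
#' (over comparable sites) between any sequence of group 1 and any of group
#' 2. The two need not agree, because median vectors can shorten a network
#' path only down to, never below, the metric distance.
#'
#' @param aln Alignment tibble.
#' @param popmap Population map with two groups.
#' @return Minimum cross-group distance (number of differing sites).
#' @export
min_intergroup_distance <- function(aln, popmap) {
  pm <- validate_popmap(aln$id, popmap)
  groups <- unique(pm$group)
  if (length(groups) != 2) abort("exactly two groups are required")
  d <- distance_matrix(aln, "differences")
  min(d[pm$group == groups[1], pm$group == groups[2]])
}

#' Export a haplotype network
#'
#' @param net A `haplotype_network`.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"` (TSV `node1 node2 steps`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    readr::write_tsv(net$edges, path, progress = FALSE)
  }
  invisible(path)
}
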