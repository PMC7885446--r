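## mjnetwork: median-joining haplotype networks and star-shape summaries.

## Minimum-spanning-network adjacency with epsilon relaxation.
## An edge (u, v) belongs to the network iff d(u, v) <= J(u, v) + eps,
## where J is the single-linkage merge level (the minimax path distance) --
## at eps = 0 this keeps every co-minimal alternative connection, the
## classic MSN.
.msn_adjacency <- function(D, eps = 0) {
  n <- nrow(D)
  A <- matrix(FALSE, n, n)
  if (n < 2L) return(A)
  if (n == 2L) {
    A[1, 2] <- A[2, 1] <- TRUE
    return(A)
  }
  J <- as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(D), method = "single")))
  A <- D <= J + eps
  diag(A) <- FALSE
  A
}

## Total weight of a minimum spanning tree (Prim), used as the network
## cost criterion for accepting median vectors.
.mst_cost <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1L))
  mind <- D[1, ]
  cost <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!intree)
    v <- cand[which.min(mind[cand])]
    cost <- cost + mind[v]
    intree[v] <- TRUE
    mind <- pmin(mind, D[v, ])
  }
  cost
}

## Site-wise majority consensus of three sequences (character vectors over
## the variable columns). Missing states are ignored; a three-way tie keeps
## the first sequence's state (deterministic).
.triplet_median <- function(a, b, c) {
  out <- a
  for (j in seq_along(a)) {
    st <- c(a[j], b[j], c[j])
    st <- st[st %in% .BASES]
    if (!length(st)) {
      out[j] <- "N"
      next
    }
    tab <- table(st)
    if (max(tab) >= 2L) {
      out[j] <- names(tab)[which.max(tab)]
    } else {
      out[j] <- st[1]
    }
  }
  out
}

## Pairwise-deletion Hamming distances between rows of a character matrix.
.char_dist <- function(mat) {
  as.matrix(pairwise_differences(mat)$diffs)
}

#' Median-joining haplotype network
#'
#' Builds a Bandelt-style median-joining network over the haplotypes of a
#' sample: (1) the epsilon-relaxed minimum spanning network over sampled
#' haplotypes, (2) site-wise majority medians of triplets connected within
#' the current network are added whenever they reduce the total network
#' (minimum-spanning) cost -- one best median per round, ties broken by
#' generation order -- iterated to fixation, (3) median vectors of degree
#' < 3 are pruned. Constant alignment columns are dropped before
#' construction (they cannot affect any distance). The construction is
#' fully deterministic.
#'
#' @param table A `hap_table` from [collapse_haplotypes()] (or a
#'   [hap_alignment], collapsed on the fly).
#' @param epsilon Relaxation parameter of the spanning network (default 0,
#'   the usual default in median-joining software).
#' @param max_medians Safety cap on the number of inferred median vectors.
#' @return Object of class `haplo_network`: list with `nodes` (data frame:
#'   `id`, `frequency`, `group`, `is_median`), `edges` (data frame: `from`,
#'   `to`, `weight` = substitutions between endpoints), `epsilon`, and
#'   `sequences` (node sequences over the variable columns, for
#'   inspection).
#' @export
median_joining <- function(table, epsilon = 0, max_medians = 64L) {
  if (inherits(table, "hap_alignment")) table <- collapse_haplotypes(table)
  stopifnot(inherits(table, "hap_table"))
  m <- table$k_obs
  code <- .encode(table$sequences)
  varcols <- which(apply(code, 2L, function(z) {
    z <- z[!is.na(z)]
    length(z) > 0L && any(z != z[1L])
  }))
  seqs <- table$sequences[, varcols, drop = FALSE]
  node_seq <- lapply(seq_len(m), function(i) seqs[i, ])
  node_key <- vapply(node_seq, paste0, character(1), collapse = "")
  if (m == 1L) {
    nodes <- data.frame(
      id = "H1", frequency = table$frequency, group = table$group,
      is_median = FALSE, stringsAsFactors = FALSE
    )
    return(structure(
      list(
        nodes = nodes,
        edges = data.frame(from = character(), to = character(), weight = integer()),
        epsilon = epsilon, sequences = node_seq, n_sampled = 1L
      ),
      class = "haplo_network"
    ))
  }

  repeat {
    nn <- length(node_seq)
    mat <- do.call(rbind, node_seq)
    D <- .char_dist(mat)
    A <- .msn_adjacency(D, epsilon)
    base_cost <- .mst_cost(D)
    ## candidate medians from triplets with at least two edges inside the
    ## current network
    cand <- list()
    ckey <- character(0)
    for (i in seq_len(nn - 2L)) {
      for (j in seq((i + 1L), nn - 1L)) {
        for (l in seq((j + 1L), nn)) {
          if (A[i, j] + A[i, l] + A[j, l] < 2L) next
          med <- .triplet_median(node_seq[[i]], node_seq[[j]], node_seq[[l]])
          key <- paste0(med, collapse = "")
          if (key %in% node_key || key %in% ckey) next
          cand[[length(cand) + 1L]] <- med
          ckey <- c(ckey, key)
        }
      }
    }
    if (!length(cand)) break
    ## cost of adding each candidate as a Steiner point
    gain <- vapply(cand, function(med) {
      dm <- .char_dist(rbind(mat, med))
      .mst_cost(dm) - base_cost
    }, numeric(1))
    best <- which(gain < -1e-9)
    if (!length(best)) break
    pick <- best[which.min(gain[best])]
    node_seq[[length(node_seq) + 1L]] <- cand[[pick]]
    node_key <- c(node_key, ckey[pick])
    if (length(node_seq) - m >= max_medians) {
      warning("median-vector cap reached; network may be incomplete")
      break
    }
  }

  ## prune median vectors of degree < 3
  repeat {
    mat <- do.call(rbind, node_seq)
    D <- .char_dist(mat)
    A <- .msn_adjacency(D, epsilon)
    deg <- rowSums(A)
    drop <- which(seq_along(node_seq) > m & deg < 3L)
    if (!length(drop)) break
    node_seq <- node_seq[-drop]
  }

  nn <- length(node_seq)
  ids <- c(rownames(table$sequences), if (nn > m) paste0("mv", seq_len(nn - m)))
  nodes <- data.frame(
    id = ids,
    frequency = c(table$frequency, rep(0L, nn - m)),
    group = c(table$group, rep(NA_character_, nn - m)),
    is_median = c(rep(FALSE, m), rep(TRUE, nn - m)),
    stringsAsFactors = FALSE
  )
  ut <- which(A & upper.tri(A), arr.ind = TRUE)
  edges <- data.frame(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    weight = D[ut], stringsAsFactors = FALSE
  )
  structure(
    list(
      nodes = nodes, edges = edges, epsilon = epsilon,
      sequences = node_seq, n_sampled = m
    ),
    class = "haplo_network"
  )
}

#' Convert a haplotype network to an igraph graph
#' @param net A `haplo_network`.
#' @return An undirected `igraph` graph with node attributes `frequency`,
#'   `group`, `is_median` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = net$nodes)
}

#' Write a haplotype network to GraphML plus TSV tables
#'
#' @param net A `haplo_network`.
#' @param graphml Output GraphML path (or `NULL` to skip).
#' @param nodes_tsv,edges_tsv Optional TSV outputs for the node and edge
#'   tables.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, graphml = NULL, nodes_tsv = NULL, edges_tsv = NULL) {
  stopifnot(inherits(net, "haplo_network"))
  if (!is.null(graphml)) {
    g <- as_igraph(net)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(nodes_tsv)) {
    utils::write.table(net$nodes, nodes_tsv,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  if (!is.null(edges_tsv)) {
    utils::write.table(net$edges, edges_tsv,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  invisible(net)
}

#' Star-shape summary of a haplotype network
#'
#' Descriptive summary of how star-like a network is: the hub is the
#' sampled haplotype of maximal degree (ties broken by higher frequency,
#' then input order), and the fraction reports how many of the other
#' sampled haplotypes sit one edge away from it. Star-shaped clusters --
#' one frequent central haplotype with many one-step derivatives -- are the
#' classic network signature of rapid expansion. No significance is
#' attached.
#'
#' @param net A `haplo_network`.
#' @return List with `hub` (node id), `hub_degree`, and `fraction_1step`
#'   (fraction of the other sampled haplotypes adjacent to the hub).
#' @export
star_summary <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  ids <- net$nodes$id
  deg <- stats::setNames(rep(0L, length(ids)), ids)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  samp <- net$nodes[!net$nodes$is_median, ]
  ord <- order(-deg[samp$id], -samp$frequency, seq_len(nrow(samp)))
  hub <- samp$id[ord[1]]
  nbr <- unique(c(
    net$edges$to[net$edges$from == hub],
    net$edges$from[net$edges$to == hub]
  ))
  others <- setdiff(samp$id, hub)
  frac <- if (length(others)) length(intersect(nbr, others)) / length(others) else 1
  list(hub = hub, hub_degree = unname(deg[hub]), fraction_1step = frac)
}

#' @export
print.haplo_network <- function(x, ...) {
  nmed <- sum(x$nodes$is_median)
  cat(sprintf(
    "Median-joining network: %d sampled haplotypes, %d median vector(s), %d edges (epsilon = %g)\n",
    x$n_sampled, nmed, nrow(x$edges), x$epsilon
  ))
  invisible(x)
}
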