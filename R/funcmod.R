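#' Assign network genes to functional modules
#'
#' For every gene set, records the member genes present in the network and
#' the intra-module link set (network edges with both endpoints in the
#' module). A gene may belong to several modules. Modules below
#' `size_floor` genes are flagged (for display filtering), not dropped.
#'
#' @param network a non-empty `state_network`.
#' @param sets a [gene_sets()] collection.
#' @param size_floor display floor for module size (default 70).
#' @return a list of class `module_assignment`: `modules` (name -> member
#'   genes in the network), `links` (name -> intra-module edge data frame),
#'   `flagged_small`, `network_edges`
#' @export
assign_modules <- function(network, sets, size_floor = 70L) {
  if (!length(sets)) stop("empty gene-set collection")
  edges <- network$edges
  modules <- lapply(sets, function(s) intersect(network$genes, s))
  links <- lapply(sets, function(s) {
    keep <- edges$gene_a %in% s & edges$gene_b %in% s
    edges[keep, c("gene_a", "gene_b"), drop = FALSE]
  })
  structure(list(modules = modules, links = links,
                 flagged_small = names(modules)[lengths(modules) < size_floor],
                 network_edges = edges[, c("gene_a", "gene_b"), drop = FALSE]),
            class = "module_assignment")
}

#' Reduce a network to its function-function network (FFN)
#'
#' Nodes are functional modules weighted by size and intra-module links per
#' gene; edges between two modules are weighted by the number of network
#' links with one endpoint in each. With multi-membership a network link
#' can contribute to several module pairs (documented double counting).
#'
#' @param assignment a [assign_modules()] result.
#' @return a list of class `ffn`: `nodes` (data frame `module`, `n_genes`,
#'   `intra_links`, `links_per_gene`) and `edges` (data frame `module_a`,
#'   `module_b`, `weight`)
#' @export
reduce_to_ffn <- function(assignment) {
  mods <- assignment$modules
  nm <- names(mods)
  nodes <- data.frame(module = nm,
                      n_genes = lengths(mods),
                      intra_links = vapply(assignment$links, nrow, 1L),
                      stringsAsFactors = FALSE, row.names = NULL)
  nodes$links_per_gene <- ifelse(nodes$n_genes > 0,
                                 nodes$intra_links / nodes$n_genes, 0)
  ed <- assignment$network_edges
  pairs <- utils::combn(seq_along(nm), 2L)
  w <- apply(pairs, 2L, function(pr) {
    m1 <- mods[[pr[1L]]]; m2 <- mods[[pr[2L]]]
    sum((ed$gene_a %in% m1 & ed$gene_b %in% m2) |
          (ed$gene_a %in% m2 & ed$gene_b %in% m1))
  })
  edges <- data.frame(module_a = nm[pairs[1L, ]], module_b = nm[pairs[2L, ]],
                      weight = w, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "ffn")
}

.link_keys <- function(links) {
  if (!nrow(links)) return(character(0))
  paste(pmin(links$gene_a, links$gene_b),
        pmax(links$gene_a, links$gene_b), sep = "\r")
}

#' Percentage overlap of a module's link sets between two networks
#'
#' `100 * |L_A intersect L_B| / min(|L_A|, |L_B|)`, where L is the
#' intra-module link set; symmetric in the two networks.
#'
#' @param assignment_a,assignment_b [assign_modules()] results of the two
#'   networks (same set collection).
#' @param module a module name with >= 1 link in each network.
#' @return the overlap percentage
#' @export
overlap_percentage <- function(assignment_a, assignment_b, module) {
  la <- assignment_a$links[[module]]
  lb <- assignment_b$links[[module]]
  if (is.null(la) || is.null(lb)) stop("unknown module: ", module)
  if (!nrow(la) || !nrow(lb))
    stop("module '", module, "' has no links in one of the networks")
  ka <- .link_keys(la); kb <- .link_keys(lb)
  100 * length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Hypergeometric gene-set enrichment
#'
#' Per set: the upper-tail hypergeometric probability of observing at least
#' the overlap between the selection and the set within the universe, with
#' BH adjustment across sets. (The plain, unconditional test; no ontology-
#' graph conditioning.)
#'
#' @param selection character vector of selected genes, a subset of
#'   `universe`.
#' @param sets a [gene_sets()] collection (members are intersected with the
#'   universe).
#' @param universe character vector of background genes (non-empty).
#' @return a data frame: `set`, `overlap`, `set_size`, `selection_size`,
#'   `universe_size`, `pct`, `p`, `p_adj`
#' @export
hypergeom_enrich <- function(selection, sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(toupper(universe))
  selection <- unique(toupper(selection))
  out_of <- setdiff(selection, universe)
  if (length(out_of))
    stop("selection gene(s) outside the universe: ",
         paste(utils::head(out_of, 5L), collapse = ", "))
  N <- length(universe); n <- length(selection)
  rows <- lapply(names(sets), function(nm) {
    K <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], selection))
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, selection_size = n,
               universe_size = N, pct = if (n > 0) 100 * k / n else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
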