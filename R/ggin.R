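#' Configuration for state-specific network construction
#'
#' @param p0 Pearson p-value threshold for edge inclusion (default 0.01).
#' @param subsample_size arrays per network (default 8; network properties
#'   are sample-size dependent, so every network is built from the same
#'   number of arrays).
#' @param n_subsamples number of networks per state when the state has more
#'   samples than `subsample_size` (default 100).
#' @param aggregate per-gene ensemble aggregation of degree / clustering
#'   coefficient: `"mean"`, `"median"`, or `"single_network"` (first
#'   network only).
#' @param seed RNG seed for subsample draws.
#' @return an object of class `ggin_config`
#' @export
ggin_config <- function(p0 = 0.01, subsample_size = 8L, n_subsamples = 100L,
                        aggregate = c("mean", "median", "single_network"),
                        seed = 1L) {
  if (p0 <= 0 || p0 > 1) stop("p0 must be in (0, 1]")
  if (subsample_size < 3L) stop("subsample_size must be >= 3")
  structure(list(p0 = p0, subsample_size = as.integer(subsample_size),
                 n_subsamples = as.integer(n_subsamples),
                 aggregate = match.arg(aggregate), seed = as.integer(seed)),
            class = "ggin_config")
}

#' Pearson correlation with a two-sided p-value
#'
#' The default p-value is the two-sided tail of
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom; the
#' permutation mode instead permutes one vector and counts `|r*| >= |r|`
#' with the add-one estimator.
#'
#' @param a,b equal-length numeric vectors, n >= 3, nonzero variance.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations for the permutation mode.
#' @param seed seed for the permutation mode.
#' @return a list with `r` and `p`
#' @export
pearson_p <- function(a, b, method = c("t", "permutation"),
                      n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("vectors must have equal length")
  n <- length(a)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero-variance vector")
  r <- stats::cor(a, b)
  if (method == "t") {
    p <- .pearson_t_p(r, n)
  } else {
    set.seed(seed)
    az <- a - mean(a); bz <- b - mean(b)
    denom <- sqrt(sum(az^2) * sum(bz^2))
    robs <- abs(sum(az * bz) / denom)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      rp <- abs(sum(az * bz[sample.int(n)]) / denom)
      if (rp >= robs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
  }
  list(r = r, p = p)
}

# two-sided t-based Pearson p, vectorised; |r| ~ 1 handled as p = 0
.pearson_t_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  d <- 1 - r^2
  p <- ifelse(d < 1e-14, 0,
              2 * stats::pt(-abs(r) * sqrt((n - 2) / pmax(d, 1e-14)), n - 2))
  pmin(p, 1)
}

# Map PPI edges onto the study's gene order; universe = measured genes that
# are PPI nodes.
.ggin_prep <- function(study, ppi) {
  genes <- rownames(study$values)
  ia <- match(ppi$edges$a, genes)
  ib <- match(ppi$edges$b, genes)
  keep <- !is.na(ia) & !is.na(ib)
  list(genes = genes, universe = intersect(genes, ppi$nodes),
       ia = ia[keep], ib = ib[keep])
}

# Row-centered, L2-normalised matrix; zero-variance rows become NaN rows.
.row_norm <- function(x) {
  xc <- x - rowMeans(x)
  s <- sqrt(rowSums(xc^2))
  xc / s
}

# Correlation over the mapped PPI edges for one column subset; returns kept
# edge indices (into prep$ia) plus r, p.
.net_edges <- function(xn, ia, ib, p0, n) {
  r <- rowSums(xn[ia, , drop = FALSE] * xn[ib, , drop = FALSE])
  p <- .pearson_t_p(r, n)
  keep <- which(!is.na(r) & p <= p0)
  list(idx = keep, r = r[keep], p = p[keep])
}

.state_network <- function(state, id, gene_a, gene_b, r, p) {
  structure(list(state = state, id = id,
                 edges = data.frame(gene_a = gene_a, gene_b = gene_b,
                                    r = r, p = p, stringsAsFactors = FALSE),
                 genes = sort(unique(c(gene_a, gene_b)))),
            class = "state_network")
}

#' @export
print.state_network <- function(x, ...) {
  cat(sprintf("state_network [%s/%s]: %d genes, %d edges\n",
              x$state, as.character(x$id), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Build one state-specific gene-gene interaction network
#'
#' A PPI edge whose both genes are measured becomes a network edge iff the
#' two-sided Pearson p-value of the pair, computed over the supplied arrays,
#' is at most `p0`. Only genes incident to at least one kept edge are
#' network nodes. Zero-variance genes are skipped with a warning.
#'
#' @param study an `expression_study` holding one state's selected arrays
#'   (subset it with [subset_samples()] first if needed).
#' @param ppi a `ppi_graph`.
#' @param config a [ggin_config()].
#' @param state optional state label override (defaults to the single state
#'   present in the study design).
#' @return an object of class `state_network`
#' @export
build_network <- function(study, ppi, config = ggin_config(), state = NULL) {
  if (ncol(study$values) < 3L) stop("need at least 3 arrays")
  if (is.null(state)) {
    st <- unique(unname(study$design))
    if (length(st) != 1L)
      stop("study spans several states; subset to one state or pass 'state'")
    state <- st
  }
  prep <- .ggin_prep(study, ppi)
  xn <- .row_norm(study$values)
  nzv <- sum(!is.finite(xn[, 1L]))
  if (nzv > 0)
    warning(sprintf("skipping %d zero-variance gene(s)", nzv))
  e <- .net_edges(xn, prep$ia, prep$ib, config$p0, ncol(study$values))
  .state_network(state, "all",
                 prep$genes[prep$ia[e$idx]], prep$genes[prep$ib[e$idx]],
                 e$r, e$p)
}

#' Build the subsample ensemble of networks for one state
#'
#' If the state has exactly `subsample_size` samples a single network is
#' built from all of them; otherwise `n_subsamples` networks are built, each
#' from a seeded random draw of `subsample_size` arrays without replacement.
#'
#' @param study the full multi-state `expression_study`.
#' @param state the state label.
#' @param ppi a `ppi_graph`.
#' @param config a [ggin_config()].
#' @return a list of `state_network` objects
#' @export
subsample_ensemble <- function(study, state, ppi, config = ggin_config()) {
  if (!state %in% study$states) stop("state absent from design: ", state)
  smp <- state_samples(study, state)
  k <- config$subsample_size
  if (length(smp) < k)
    stop(sprintf("state %s has %d samples, fewer than subsample_size = %d",
                 state, length(smp), k))
  prep <- .ggin_prep(study, ppi)
  vals <- study$values[, smp, drop = FALSE]
  if (length(smp) == k) {
    xn <- .row_norm(vals)
    e <- .net_edges(xn, prep$ia, prep$ib, config$p0, k)
    return(list(.state_network(state, 1L,
                               prep$genes[prep$ia[e$idx]],
                               prep$genes[prep$ib[e$idx]], e$r, e$p)))
  }
  set.seed(config$seed + sum(utf8ToInt(state)))
  lapply(seq_len(config$n_subsamples), function(i) {
    cols <- sample.int(length(smp), k)
    xn <- .row_norm(vals[, cols, drop = FALSE])
    e <- .net_edges(xn, prep$ia, prep$ib, config$p0, k)
    .state_network(state, i,
                   prep$genes[prep$ia[e$idx]], prep$genes[prep$ib[e$idx]],
                   e$r, e$p)
  })
}

# local clustering coefficients from an integer edge list; returns a vector
# named by node id for all incident nodes
.local_cc <- function(ia, ib) {
  nb <- split(c(ib, ia), c(ia, ib))
  cc <- vapply(nb, function(v) {
    k <- length(v)
    if (k < 2L) return(0)
    # e = edges among neighbors; each such edge found twice below
    twice_e <- sum(vapply(as.character(v), function(u)
      length(intersect(nb[[u]], v)), 1L))
    twice_e / (k * (k - 1))
  }, 1)
  cc
}

#' Local clustering coefficient C = 2e / (k (k - 1))
#'
#' `e` is the number of edges among the gene's `k` neighbors; genes of
#' degree 1 have C = 0 by convention.
#'
#' @param network a `state_network`.
#' @param gene a gene in the network, or `NULL` for all nodes.
#' @return a single value, or a named vector over all network nodes
#' @export
clustering_coefficient <- function(network, gene = NULL) {
  nodes <- network$genes
  ia <- match(network$edges$gene_a, nodes)
  ib <- match(network$edges$gene_b, nodes)
  cc <- .local_cc(ia, ib)
  out <- stats::setNames(rep(0, length(nodes)), nodes)
  out[as.integer(names(cc))] <- cc
  if (is.null(gene)) return(out)
  if (!gene %in% nodes) stop("gene not in network: ", gene)
  unname(out[gene])
}

#' Least-squares power-law exponent of a degree histogram
#'
#' Slope of the least-squares line of `log10(count)` on `log10(k)` over
#' degrees k >= 1 with nonzero count. Descriptive, not inferential.
#'
#' @param k degrees (>= 1).
#' @param count occurrence count per degree.
#' @return the fitted slope (NA if fewer than 2 usable degrees)
#' @export
power_law_fit <- function(k, count) {
  keep <- k >= 1 & count > 0
  k <- k[keep]; count <- count[keep]
  if (length(k) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(log10(count) ~ log10(k)))[2L])
}

#' Mean degree of a simple graph
#' @param n_nodes,n_edges node and edge counts.
#' @return `2 * n_edges / n_nodes`
#' @export
mean_degree <- function(n_nodes, n_edges) 2 * n_edges / n_nodes

#' Structural summary of a network
#'
#' @param network a non-empty `state_network`.
#' @return a list: `n_nodes`, `n_edges`, `mean_degree`,
#'   `power_law_exponent`, `mean_clustering`, `giant_component_size`
#' @export
summarize_network <- function(network) {
  if (nrow(network$edges) == 0L) stop("empty network")
  nodes <- network$genes
  deg <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                      levels = nodes))
  dt <- table(as.integer(deg))
  g <- igraph::graph_from_data_frame(network$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  list(n_nodes = length(nodes),
       n_edges = nrow(network$edges),
       mean_degree = mean_degree(length(nodes), nrow(network$edges)),
       power_law_exponent = power_law_fit(as.integer(names(dt)),
                                          as.integer(dt)),
       mean_clustering = mean(clustering_coefficient(network)),
       giant_component_size = max(igraph::components(g)$csize))
}

#' Ensemble-aggregated per-gene network statistics
#'
#' Degree D is aggregated with absent-from-network counted as 0; the
#' clustering coefficient C is aggregated over the networks in which the
#' gene is present (0 if never present). `presence_fraction` is the
#' fraction of ensemble networks containing the gene.
#'
#' @param ensemble a non-empty list of `state_network` (one state).
#' @param gene_universe genes to report (e.g. measured genes that are PPI
#'   nodes).
#' @param aggregate `"mean"` (default), `"median"`, or `"single_network"`.
#' @return a data frame: `gene`, `state`, `D`, `C`, `presence_fraction`
#' @export
aggregate_gene_stats <- function(ensemble, gene_universe,
                                 aggregate = c("mean", "median",
                                               "single_network")) {
  aggregate <- match.arg(aggregate)
  if (!length(ensemble)) stop("empty ensemble")
  if (aggregate == "single_network") ensemble <- ensemble[1L]
  nU <- length(gene_universe)
  nN <- length(ensemble)
  Dm <- matrix(0, nU, nN)
  Cm <- matrix(0, nU, nN)
  Pm <- matrix(FALSE, nU, nN)
  for (j in seq_len(nN)) {
    net <- ensemble[[j]]
    if (!nrow(net$edges)) next
    deg <- table(c(net$edges$gene_a, net$edges$gene_b))
    gi <- match(names(deg), gene_universe)
    ok <- !is.na(gi)
    Dm[gi[ok], j] <- as.integer(deg)[ok]
    cc <- clustering_coefficient(net)
    ci <- match(names(cc), gene_universe)
    ok <- !is.na(ci)
    Cm[ci[ok], j] <- cc[ok]
    Pm[ci[ok], j] <- TRUE
  }
  pres <- rowSums(Pm)
  if (aggregate == "median") {
    D <- apply(Dm, 1L, stats::median)
    C <- vapply(seq_len(nU), function(i)
      if (pres[i] > 0) stats::median(Cm[i, Pm[i, ]]) else 0, 1)
  } else {
    D <- rowMeans(Dm)
    C <- ifelse(pres > 0, rowSums(Cm) / pmax(pres, 1), 0)
  }
  data.frame(gene = gene_universe,
             state = if (nN) ensemble[[1L]]$state else NA_character_,
             D = D, C = C, presence_fraction = pres / nN,
             stringsAsFactors = FALSE)
}

#' Joint degree x clustering-coefficient profile of an ensemble
#'
#' Percentage of shown genes per (degree, C-range) cell; genes of degree 1
#' are excluded (a degree-1 gene has no defined neighbourhood density
#' beyond C = 0). Percentages are per network, averaged over the ensemble
#' unless `per_network = TRUE`.
#'
#' @param ensemble a list of `state_network`.
#' @param c_breaks clustering-coefficient bin boundaries.
#' @param per_network return one row set per network instead of the
#'   ensemble average.
#' @return a data frame: (`network`,) `degree`, `c_range`, `pct`
#' @export
degree_cc_profile <- function(ensemble, c_breaks = seq(0, 1, 0.25),
                              per_network = FALSE) {
  if (!length(ensemble)) stop("empty ensemble")
  one <- function(net, id) {
    if (!nrow(net$edges)) return(NULL)
    deg <- table(c(net$edges$gene_a, net$edges$gene_b))
    cc <- clustering_coefficient(net)
    k <- as.integer(deg[names(cc)])
    shown <- k >= 2L
    if (!any(shown)) return(NULL)
    bins <- cut(cc[shown], breaks = c_breaks, include.lowest = TRUE)
    tab <- table(degree = k[shown], c_range = bins)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df$degree <- as.integer(df$degree)
    df$pct <- 100 * df$Freq / sum(shown)
    df$Freq <- NULL
    df$network <- id
    df
  }
  rows <- do.call(rbind, Map(one, ensemble, seq_along(ensemble)))
  if (is.null(rows)) stop("no genes of degree >= 2 in the ensemble")
  if (per_network) return(rows[, c("network", "degree", "c_range", "pct")])
  agg <- stats::aggregate(pct ~ degree + c_range, rows,
                          FUN = function(x) sum(x) / length(ensemble))
  agg[order(agg$degree, agg$c_range), ]
}
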