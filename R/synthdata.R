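#' Configuration for the synthetic multi-state cohort generator
#'
#' The generator plants co-expression modules whose within-module correlation
#' rho_s and mean shift delta_s (log2 units) change along the state sequence,
#' on top of independent gene-wise noise, and lays a scale-free PPI scaffold
#' over the gene universe with all within-module pairs added as edges (so
#' planted correlation edges can pass the PPI filter downstream).
#'
#' @param n_genes number of genes in the universe.
#' @param states named integer vector: state label -> sample count (ordered;
#'   counts must be >= 3).
#' @param ppi_degree_exponent power-law exponent of the scaffold's expected
#'   degree distribution.
#' @param n_ppi_edges number of scaffold edges before module pairs are added.
#' @param modules list of planted modules, each a list with elements
#'   `genes` (member symbols), `rho` (per-state within-module correlation,
#'   named by state, each in [0, 1)), `delta` (per-state mean shift, log2
#'   units, named by state).
#' @param noise_sd standard deviation of the gene-wise noise (log2 units).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   intensity.
#' @param seed RNG seed; identical seed implies identical output.
#' @return an object of class `synth_config`
#' @export
synth_config <- function(n_genes = 600,
                         states = c(Nor = 8L, Ade = 15L, IBD = 15L, CRC = 15L),
                         ppi_degree_exponent = 2.5,
                         n_ppi_edges = 1500L,
                         modules = list(),
                         noise_sd = 1,
                         baseline_mean = 8,
                         baseline_sd = 1.5,
                         seed = 1L) {
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("'states' must be a named vector of sample counts")
  if (any(states < 3L)) stop("per-state sample counts must be >= 3")
  universe <- sprintf("G%04d", seq_len(n_genes))
  for (m in modules) {
    if (!all(c("genes", "rho", "delta") %in% names(m)))
      stop("each module needs 'genes', 'rho', 'delta'")
    if (!all(m$genes %in% universe))
      stop("module member(s) outside the gene universe")
    if (any(m$rho < 0 | m$rho >= 1))
      stop("module rho must satisfy 0 <= rho < 1")
    if (!all(names(states) %in% names(m$rho)) ||
        !all(names(states) %in% names(m$delta)))
      stop("module rho/delta must be named by state")
  }
  all_members <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(all_members))
    stop("planted modules must be disjoint")
  structure(list(n_genes = n_genes, states = states,
                 ppi_degree_exponent = ppi_degree_exponent,
                 n_ppi_edges = n_ppi_edges, modules = modules,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default planted progression modules
#'
#' Disjoint modules of `size` genes each whose correlation and mean shift
#' grow along the state sequence; used by the `paper_shaped` fixture.
#'
#' @param n_modules number of modules.
#' @param size genes per module.
#' @param rho,delta per-state correlation / mean shift (named by state).
#' @param offset index of the first member gene.
#' @return a list suitable for the `modules` field of [synth_config()]
#' @export
planted_modules <- function(n_modules = 3L, size = 12L,
                            rho = c(Nor = 0.2, Ade = 0.6, IBD = 0.6, CRC = 0.9),
                            delta = c(Nor = 0, Ade = 1, IBD = 1, CRC = 2),
                            offset = 1L) {
  lapply(seq_len(n_modules), function(k) {
    first <- offset + (k - 1L) * size
    list(genes = sprintf("G%04d", first:(first + size - 1L)),
         rho = rho, delta = delta)
  })
}

#' Simulate a multi-state cohort with planted progression structure
#'
#' Module members in state s are drawn as
#' `baseline + delta_s + noise_sd * (sqrt(rho_s) f + sqrt(1 - rho_s) eps)`
#' with a shared per-sample factor f, which gives expected pairwise
#' correlation exactly rho_s between members; all other genes are
#' independent `baseline + noise_sd * eps`. The PPI scaffold is a static
#' power-law (fitness) graph with all within-module pairs added.
#'
#' @param config a [synth_config()]
#' @return a list with elements `study` ([expression_study()]), `ppi`
#'   ([ppi_graph()]), and `truth` (list: `trend_genes`, `module_map`,
#'   `config`).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  st_labels <- names(config$states)
  samples <- unlist(lapply(st_labels, function(s)
    sprintf("%s_%02d", s, seq_len(config$states[[s]]))))
  design <- stats::setNames(rep(st_labels, times = config$states), samples)
  baseline <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
  vals <- baseline +
    matrix(stats::rnorm(config$n_genes * length(samples), 0, config$noise_sd),
           nrow = config$n_genes, dimnames = list(genes, samples))
  for (m in config$modules) {
    gi <- match(m$genes, genes)
    for (s in st_labels) {
      cols <- which(design == s)
      rho <- m$rho[[s]]; delta <- m$delta[[s]]
      f <- stats::rnorm(length(cols))
      # replace the independent draw by the shared-factor construction, at
      # the same marginal sd: sqrt(rho) f + sqrt(1 - rho) eps
      eps <- matrix(stats::rnorm(length(gi) * length(cols)),
                    nrow = length(gi))
      vals[gi, cols] <- baseline[gi] + delta + config$noise_sd *
        (sqrt(rho) * rep(f, each = length(gi)) + sqrt(1 - rho) * eps)
    }
  }
  scaffold <- igraph::sample_fitness_pl(config$n_genes, config$n_ppi_edges,
                                        exponent.out = config$ppi_degree_exponent)
  el <- igraph::as_edgelist(scaffold, names = FALSE)
  edges <- data.frame(a = genes[el[, 1L]], b = genes[el[, 2L]],
                      stringsAsFactors = FALSE)
  for (m in config$modules) {
    pairs <- utils::combn(m$genes, 2L)
    edges <- rbind(edges, data.frame(a = pairs[1L, ], b = pairs[2L, ],
                                     stringsAsFactors = FALSE))
  }
  ppi <- ppi_graph(edges)
  final <- st_labels[length(st_labels)]
  trend_genes <- unlist(lapply(config$modules, function(m)
    if (m$rho[[final]] > m$rho[[st_labels[1L]]]) m$genes else character()))
  module_map <- stats::setNames(
    lapply(config$modules, `[[`, "genes"),
    sprintf("module_%02d", seq_along(config$modules)))
  list(study = expression_study(vals, design, states = st_labels),
       ppi = ppi,
       truth = list(trend_genes = unname(trend_genes),
                    module_map = module_map, config = config))
}

#' Named deterministic fixtures
#'
#' `tiny` is a 40-gene, 3-state cohort for fast smoke tests; `paper_shaped`
#' mimics a 4-state cohort with 8/15/15/15 samples and three planted
#' 12-gene modules whose correlation grows 0.2 -> 0.6 -> 0.9 toward the
#' final disease state.
#'
#' @param profile one of `"tiny"`, `"paper_shaped"`.
#' @param seed optional seed override (default: fixed per profile, so the
#'   same profile always yields the identical fixture).
#' @return as [simulate_study()]
#' @export
make_fixture <- function(profile = c("tiny", "paper_shaped"), seed = NULL) {
  if (!is.character(profile) || !profile[1L] %in% c("tiny", "paper_shaped"))
    stop("unknown profile '", profile[1L], "'; available: tiny, paper_shaped")
  profile <- match.arg(profile)
  cfg <- switch(profile,
    tiny = synth_config(
      n_genes = 40L, states = c(Nor = 8L, Ade = 10L, CRC = 10L),
      n_ppi_edges = 80L,
      modules = planted_modules(1L, 8L,
        rho = c(Nor = 0.1, Ade = 0.5, CRC = 0.9),
        delta = c(Nor = 0, Ade = 1, CRC = 2)),
      seed = if (is.null(seed)) 42L else seed),
    paper_shaped = synth_config(
      n_genes = 600L, states = c(Nor = 8L, Ade = 15L, IBD = 15L, CRC = 15L),
      n_ppi_edges = 1500L,
      modules = planted_modules(3L, 12L),
      seed = if (is.null(seed)) 20130614L else seed))
  simulate_study(cfg)
}
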