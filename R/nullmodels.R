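#' Type-1 randomization: scramble each gene's intensities across all arrays
#'
#' One sweep over all genes; each gene's intensity vector is independently
#' permuted across the entire set of arrays (states mixed). The per-gene
#' value multiset is conserved exactly; pairwise intensity correlation is
#' destroyed.
#'
#' @param study an `expression_study`.
#' @param seed RNG seed.
#' @return a new `expression_study` with permuted values
#' @export
randomize_type1 <- function(study, seed = 1L) {
  set.seed(seed)
  v <- study$values
  for (i in seq_len(nrow(v))) v[i, ] <- v[i, sample.int(ncol(v))]
  expression_study(v, study$design, states = study$states)
}

# sample m distinct unordered pairs (no self-pairs) from 'universe':
# draw linear pair indices without replacement and unrank them to (i < j)
.sample_pairs <- function(universe, m, max_pairs) {
  u <- length(universe)
  t <- as.numeric(sample.int(max_pairs, m))
  f <- function(i) i * u - i * (i + 1) / 2  # pairs with first index <= i
  i <- ceiling(((2 * u - 1) - sqrt((2 * u - 1)^2 - 8 * t)) / 2)
  i <- i - (f(i - 1) >= t)  # float-safety corrections
  i <- i + (f(i) < t)
  j <- i + (t - f(i - 1))
  cbind(as.integer(i), as.integer(j))
}

#' Type-2 randomization: reassign every network link to a random gene pair
#'
#' The number of links is conserved; the rewired links are distinct
#' unordered pairs sampled uniformly from the gene universe (no
#' self-loops), so the topology -- in particular the degree sequence -- is
#' not conserved.
#'
#' @param network a `state_network`.
#' @param gene_universe genes eligible as endpoints (>= 3; typically the
#'   measured genes that are PPI nodes).
#' @param seed RNG seed.
#' @return a rewired `state_network` (correlation metadata dropped)
#' @export
randomize_type2 <- function(network, gene_universe, seed = 1L) {
  u <- length(gene_universe)
  if (u < 3L) stop("gene universe must have >= 3 genes")
  m <- nrow(network$edges)
  max_pairs <- u * (u - 1) / 2
  if (m > max_pairs)
    stop(sprintf("cannot place %d distinct links among %d genes (max %d)",
                 m, u, as.integer(max_pairs)))
  if (m == 0L) return(network)
  set.seed(seed)
  pairs <- .sample_pairs(gene_universe, m, max_pairs)
  .state_network(network$state, paste0(network$id, "_rewired"),
                 gene_universe[pairs[, 1L]], gene_universe[pairs[, 2L]],
                 rep(NA_real_, m), rep(NA_real_, m))
}

#' Type-3 (topology-conserving) randomization -- unsupported
#'
#' Relabelling nodes while keeping the topology is not a true
#' randomization of the network-construction process, so it is not
#' provided.
#'
#' @param ... ignored
#' @export
randomize_type3 <- function(...) {
  stop("type-3 (topology-conserving) randomization is unsupported: ",
       "it is not a true randomization")
}

#' Permutation p-value with the add-one estimator
#'
#' `p = (1 + #{null >= observed}) / (1 + N)` for direction `"greater"`
#' (`<=` for `"less"`), so p is never 0.
#'
#' @param observed the observed value.
#' @param null_values the null replicate values (>= 1).
#' @param direction `"greater"` or `"less"`.
#' @return a list of class `permutation_summary`: `observed`, `null_mean`,
#'   `null_sd`, `p_value`
#' @export
permutation_p <- function(observed, null_values,
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(null_values)) stop("empty null")
  hits <- if (direction == "greater") sum(null_values >= observed)
          else sum(null_values <= observed)
  structure(list(observed = observed,
                 null_mean = mean(null_values),
                 null_sd = stats::sd(null_values),
                 p_value = (1 + hits) / (1 + length(null_values)),
                 n = length(null_values), direction = direction),
            class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed %.4g vs null %.4g (sd %.4g), p = %.4g [N = %d]\n",
              x$direction, x$observed, x$null_mean,
              if (is.na(x$null_sd)) 0 else x$null_sd, x$p_value, x$n))
  invisible(x)
}

#' Specification of a selection pipeline for null campaigns
#'
#' @param study,ppi the observed inputs.
#' @param sequence ordered state labels (>= 3).
#' @param ggin a [ggin_config()].
#' @param top a [top_config()].
#' @param deg a [deg_config()] (used when `mode = "tps"`).
#' @param mode `"top"` or `"tps"`.
#' @param catalog optional [gene_catalog()] for hit rates.
#' @return a list of class `pipeline_spec`
#' @export
pipeline_spec <- function(study, ppi, sequence, ggin = ggin_config(),
                          top = top_config(), deg = deg_config(),
                          mode = c("top", "tps"), catalog = NULL) {
  structure(list(study = study, ppi = ppi, sequence = sequence,
                 ggin = ggin, top = top, deg = deg,
                 mode = match.arg(mode), catalog = catalog),
            class = "pipeline_spec")
}

# one full selection run; optionally rewire each built network (type-2)
.run_selection <- function(spec, study, rewire = FALSE, seed = 1L) {
  universe <- intersect(rownames(study$values), spec$ppi$nodes)
  stats_list <- list()
  for (si in seq_along(spec$sequence)) {
    s <- spec$sequence[si]
    ens <- subsample_ensemble(study, s, spec$ppi, spec$ggin)
    if (rewire)
      ens <- lapply(seq_along(ens), function(i)
        randomize_type2(ens[[i]], universe, seed = seed + 7919L * si + i))
    stats_list[[s]] <- aggregate_gene_stats(ens, universe, spec$ggin$aggregate)
  }
  rec <- trend_records(stats_list, spec$sequence)
  res <- top_select(rec, spec$top)
  if (spec$mode == "tps" && length(res$genes)) {
    first <- spec$sequence[1L]
    mk <- function(s) two_class_test(study, state_samples(study, s),
                                     state_samples(study, first))
    res <- tps_select(res, mk(spec$sequence[2L]),
                      mk(spec$sequence[length(spec$sequence)]), spec$deg)
  }
  hr <- if (!is.null(spec$catalog) && length(res$genes))
    as.numeric(hit_rate(res$genes, spec$catalog)) else NA_real_
  list(result = res, records = rec, n_selected = length(res$genes),
       hit_rate = hr)
}

#' Run a randomization null ensemble of the full selection pipeline
#'
#' Per replicate: apply type-1 randomization to the intensities (types
#' `"type1"` and `"both"`) before network construction, and/or type-2
#' rewiring to every constructed network (types `"type2"` and `"both"`),
#' rerun the selection, and record the selection size and hit rate. The
#' joint `"both"` scheme is the one used for trend-based selections.
#'
#' @param spec a [pipeline_spec()].
#' @param type `"type1"`, `"type2"`, or `"both"`.
#' @param n_replicates number of replicates (>= 1).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return a data frame of class `null_runs`: `type`, `replicate`, `seed`,
#'   `n_selected`, `hit_rate`
#' @export
null_ensemble <- function(spec, type = c("both", "type1", "type2"),
                          n_replicates = 100L, seed = 1L) {
  type <- match.arg(type)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rs <- seed + r
    st <- if (type %in% c("type1", "both"))
      randomize_type1(spec$study, seed = rs) else spec$study
    run <- .run_selection(spec, st, rewire = type %in% c("type2", "both"),
                          seed = rs)
    rows[[r]] <- data.frame(type = type, replicate = r, seed = rs,
                            n_selected = run$n_selected,
                            hit_rate = run$hit_rate,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("null_runs", "data.frame")
  out
}
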