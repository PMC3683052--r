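#' Assemble a full-run configuration
#'
#' Inputs may be given as in-memory objects or file paths (paths are loaded
#' with the corresponding reader).
#'
#' @param study an `expression_study` or expression-matrix path (then
#'   `design` must be the sample-sheet path).
#' @param ppi a `ppi_graph` or PPI TSV path.
#' @param sequences list of ordered state-label vectors (each >= 3 states).
#' @param design sample-sheet path when `study` is a path.
#' @param catalog optional `gene_catalog` or gene-list path.
#' @param ggin,top,deg,marker stage configurations.
#' @param use_tps apply the differential-expression (TPS) filter.
#' @param find_markers screen TPS selections for early-detection markers
#'   (needs two 3-state sequences sharing first and final states).
#' @param seed global seed recorded in outputs.
#' @return a list of class `run_config`
#' @export
run_config <- function(study, ppi, sequences, design = NULL, catalog = NULL,
                       ggin = ggin_config(), top = top_config(),
                       deg = deg_config(), marker = early_marker_config(),
                       use_tps = TRUE, find_markers = use_tps, seed = 1L) {
  if (is.character(study)) {
    if (is.null(design)) stop("'design' path required when 'study' is a path")
    study <- read_expression(study, design)
  }
  if (is.character(ppi)) ppi <- read_ppi(ppi)
  if (is.character(catalog)) catalog <- read_gene_list(catalog)
  if (!is.list(sequences[[1L]]) && !is.character(sequences[[1L]]))
    stop("'sequences' must be a list of state-label vectors")
  if (is.character(sequences) && !is.list(sequences))
    sequences <- list(sequences)
  for (sq in sequences) {
    bad <- setdiff(sq, study$states)
    if (length(bad))
      stop("sequence uses state(s) absent from the design: ",
           paste(bad, collapse = ", "))
    if (length(sq) < 3L) stop("each sequence needs >= 3 states")
  }
  ggin$seed <- as.integer(seed)
  structure(list(study = study, ppi = ppi, sequences = sequences,
                 catalog = catalog, ggin = ggin, top = top, deg = deg,
                 marker = marker, use_tps = use_tps,
                 find_markers = find_markers, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full trend-of-progression pipeline
#'
#' Per sequence: PPI intersection, subsample network ensembles per state,
#' per-gene degree / clustering statistics, trend selection, optional
#' differential-expression (TPS) filtering; then combination across
#' sequences, hit-rate evaluation and early-detection-marker screening.
#' State ensembles are computed once and shared between sequences. A
#' funnel report records the candidate-set size after each stage.
#'
#' @param config a [run_config()].
#' @return a list of class `top_run`: `sequences` (per-sequence list with
#'   `top`, `tps`, `records`, `hit_rate`), `combined`, `markers`, `funnel`
#'   (data frame `sequence`, `stage`, `n`), `config`
#' @export
run_top_pipeline <- function(config) {
  study <- config$study; ppi <- config$ppi
  universe <- intersect(rownames(study$values), ppi$nodes)
  needed_states <- unique(unlist(config$sequences))
  stats_by_state <- list()
  for (s in needed_states) {
    ens <- subsample_ensemble(study, s, ppi, config$ggin)
    stats_by_state[[s]] <- aggregate_gene_stats(ens, universe,
                                                config$ggin$aggregate)
  }
  deg_cache <- list()
  get_deg <- function(x, nor) {
    key <- paste(x, nor, sep = "|")
    if (is.null(deg_cache[[key]]))
      deg_cache[[key]] <<- two_class_test(study, state_samples(study, x),
                                          state_samples(study, nor))
    deg_cache[[key]]
  }
  seq_results <- list()
  funnel <- list()
  for (sq in config$sequences) {
    label <- paste(sq, collapse = "-")
    rec <- trend_records(stats_by_state[sq], sq)
    in_net <- sum(rowSums(.dmat(rec, "D") > 0) > 0)
    top <- top_select(rec, config$top)
    rows <- data.frame(
      sequence = label,
      stage = c("measured", "in_ppi", "in_network", "top"),
      n = c(nrow(study$values), length(universe), in_net,
            length(top$genes)),
      stringsAsFactors = FALSE)
    res <- list(records = rec, top = top)
    if (config$use_tps) {
      deg_x <- get_deg(sq[2L], sq[1L])
      deg_f <- get_deg(sq[length(sq)], sq[1L])
      res$tps <- tps_select(top, deg_x, deg_f, config$deg)
      rows <- rbind(rows, data.frame(sequence = label, stage = "tps",
                                     n = length(res$tps$genes),
                                     stringsAsFactors = FALSE))
    }
    final_sel <- if (config$use_tps) res$tps else res$top
    if (!is.null(config$catalog) && length(final_sel$genes))
      res$hit_rate <- hit_rate(final_sel, config$catalog)
    seq_results[[label]] <- res
    funnel[[label]] <- rows
  }
  out <- list(sequences = seq_results,
              funnel = do.call(rbind, funnel), config = config)
  if (length(seq_results) == 2L) {
    pick <- function(r) if (config$use_tps) r$tps else r$top
    out$combined <- combine_sequences(pick(seq_results[[1L]]),
                                      pick(seq_results[[2L]]))
    if (!is.null(config$catalog) && length(out$combined$genes))
      out$combined_hit_rate <- hit_rate(out$combined, config$catalog)
  }
  if (config$find_markers && config$use_tps) {
    out$markers <- list()
    labels <- names(seq_results)
    for (k in seq_along(config$sequences)) {
      sq <- config$sequences[[k]]
      if (length(sq) != 3L) next
      other <- if (length(config$sequences) == 2L) {
        osq <- config$sequences[[if (k == 1L) 2L else 1L]]
        if (length(osq) == 3L) get_deg(osq[2L], osq[1L]) else NULL
      } else NULL
      mcfg <- config$marker
      if (is.null(other)) mcfg$exclusivity <- FALSE
      out$markers[[labels[k]]] <- early_markers(
        seq_results[[k]]$tps, seq_results[[k]]$records,
        get_deg(sq[2L], sq[1L]), other, mcfg, deg_tps_config = config$deg)
    }
  }
  row.names(out$funnel) <- NULL
  class(out) <- "top_run"
  out
}

#' @export
print.top_run <- function(x, ...) {
  cat("trend-of-progression run\n")
  print(x$funnel)
  if (!is.null(x$combined))
    cat(sprintf("combined: %d genes (%d / %d / %d exclusive-A / common / exclusive-B)\n",
                x$combined$summary$n_union, x$combined$summary$n_exclusive_a,
                x$combined$summary$n_common, x$combined$summary$n_exclusive_b))
  invisible(x)
}

#' Null campaign around a completed observed run
#'
#' Reruns the selection of one sequence on randomized data
#' ([null_ensemble()]) and summarizes the observed selection size and hit
#' rate against the null distributions with add-one permutation p-values.
#'
#' @param config the [run_config()] of the observed run.
#' @param observed the completed [run_top_pipeline()] result.
#' @param sequence which sequence to test (index or label; default first).
#' @param type randomization scheme, see [null_ensemble()].
#' @param n_replicates replicates.
#' @param seed base seed.
#' @return a list: `n_selected` ([permutation_p()] summary), `hit_rate`
#'   (summary or NULL), `runs` (the null replicate table)
#' @export
run_null_campaign <- function(config, observed, sequence = 1L,
                              type = c("both", "type1", "type2"),
                              n_replicates = 100L, seed = 1L) {
  type <- match.arg(type)
  if (is.null(observed$sequences)) stop("missing observed run")
  res <- observed$sequences[[sequence]]
  sq <- if (is.numeric(sequence)) config$sequences[[sequence]]
        else config$sequences[[match(sequence, names(observed$sequences))]]
  mode <- if (config$use_tps) "tps" else "top"
  spec <- pipeline_spec(config$study, config$ppi, sq, config$ggin,
                        config$top, config$deg, mode, config$catalog)
  runs <- null_ensemble(spec, type, n_replicates, seed)
  obs_sel <- if (config$use_tps) res$tps else res$top
  out <- list(n_selected = permutation_p(length(obs_sel$genes),
                                         runs$n_selected, "greater"),
              runs = runs)
  if (!is.null(config$catalog) && length(obs_sel$genes)) {
    null_hr <- ifelse(is.na(runs$hit_rate), 0, runs$hit_rate)
    out$hit_rate <- permutation_p(as.numeric(hit_rate(obs_sel, config$catalog)),
                                  null_hr, "greater")
  }
  out
}
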