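# End-to-end pipeline: landscape -> window grid -> umbrella sampling ->
# WHAM (+ block errors) -> grid minimum-energy path -> profile ->
# stationary-state report.  A run is fully described by a run_config; the
# config hash is recorded in every artifact header so outputs are traceable,
# and reruns with the same config are byte-identical.

#' Assemble a pipeline run configuration
#'
#' @param landscape a [landscape_spec()] or a list of arguments for one.
#' @param ranges window-grid ranges (vector or per-axis list), A.
#' @param spacing window spacing, A (default 0.1).
#' @param sampler list: `n_equil`, `n_prod`, `stride`, `k_equil`, `k_prod`,
#'   `temperature`.
#' @param wham list: `bin_width`, `tol`, `min_count`, `n_blocks`, `pad`
#'   (extra bin range beyond the window range, A).
#' @param path list: `connectivity`, optional `start` / `end` bins
#'   (`c(ix, iy)`), `smoothing`, `min_prominence`.
#' @param seed master seed; per-window seeds come from [derive_seed()].
#' @return A validated `run_config`.
#' @export
run_config <- function(landscape, ranges, spacing = 0.1,
                       sampler = list(), wham = list(), path = list(),
                       seed = 1L) {
  if (!inherits(landscape, "landscape_spec"))
    landscape <- do.call(landscape_spec, landscape)
  sampler <- utils::modifyList(list(n_equil = 10000L, n_prod = 60000L,
                                    stride = 10L, k_equil = 1000,
                                    k_prod = 200, temperature = 300),
                               sampler)
  wham <- utils::modifyList(list(bin_width = 0.02, tol = 1e-6,
                                 min_count = 1L, n_blocks = 3L, pad = 0.1),
                            wham)
  path <- utils::modifyList(list(connectivity = 4, start = NULL, end = NULL,
                                 smoothing = 0, min_prominence = 0),
                            path)
  cfg <- structure(list(landscape = landscape, ranges = ranges,
                        spacing = spacing, sampler = sampler, wham = wham,
                        path = path, seed = as.integer(seed)),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks ranges/spacing commensurability, positive step counts, the
#' divisibility of the recorded production length by the block count, and
#' that at least one window would be generated -- all before any sampling.
#'
#' @param config a `run_config`.
#' @return `config`, invisibly; errors on the first violation.
#' @export
validate_config <- function(config) {
  s <- config$sampler
  if (s$n_prod <= 0 || s$n_equil < 0) stop("invalid step counts")
  if (s$n_prod %% s$stride != 0L)
    stop("n_prod must be divisible by the stride")
  nrec <- s$n_prod %/% s$stride
  if (nrec %% config$wham$n_blocks != 0L)
    stop("recorded production length (", nrec,
         ") must be divisible by n_blocks (", config$wham$n_blocks, ")")
  ranges <- config$ranges
  if (!is.list(ranges)) ranges <- list(ranges)
  if (length(ranges) == 0) stop("configuration defines zero windows")
  nw <- prod(vapply(ranges, function(r)
    round((r[2] - r[1]) / config$spacing) + 1, 1))
  if (!is.finite(nw) || nw < 1) stop("configuration defines zero windows")
  # raises on non-commensurate ranges without sampling anything:
  invisible(build_window_grid(config$ranges, config$spacing,
                              master_seed = config$seed))
  invisible(config)
}

#' Short traceability hash of a configuration
#'
#' A deterministic 32-bit polynomial hash of the JSON serialisation of the
#' configuration, written into every artifact header.
#'
#' @param config a `run_config` (or any serialisable list).
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.bin_edges_for <- function(ranges, spacing, bin_width, pad) {
  if (!is.list(ranges)) ranges <- list(ranges)
  lapply(ranges, function(r) {
    lo <- r[1] - pad; hi <- r[2] + pad
    n <- ceiling((hi - lo) / bin_width - 1e-9)
    seq(lo, by = bin_width, length.out = n + 1)
  })
}

#' Run the full umbrella-sampling / WHAM / pathway pipeline
#'
#' Stage order: landscape -> window grid -> per-window Metropolis sampling
#' -> WHAM potential of mean force (+ three-block error estimate) -> (2D
#' only) minimum-free-energy path by weighted-graph Dijkstra -> energy
#' profile vs accumulated path length -> stationary-state report.  All
#' artifacts are written to `outdir` (if given) as annotated TSV carrying
#' the config hash; a rerun with the same config is byte-identical.
#'
#' @param config a `run_config`.
#' @param outdir optional output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a bundle: list with `config`, `hash`, `windows`,
#'   `series`, `pmf`, `blocks`, and (2D) `path`, `profile`, `report`.
#' @export
run_pipeline <- function(config, outdir = NULL, quiet = TRUE) {
  validate_config(config)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(...)
  spec <- config$landscape
  s <- config$sampler
  say("stage windows")
  windows <- build_window_grid(config$ranges, config$spacing,
                               k_equil = s$k_equil, k_prod = s$k_prod,
                               n_equil = s$n_equil, n_prod = s$n_prod,
                               temperature = s$temperature,
                               master_seed = config$seed)
  say("stage sampling (", length(windows), " windows)")
  series <- lapply(windows, function(w)
    sample_window(spec, w, stride = s$stride))
  say("stage wham")
  edges <- .bin_edges_for(config$ranges, config$spacing,
                          config$wham$bin_width, config$wham$pad)
  hist <- build_histograms(series, edges)
  pmf <- solve_wham(hist, tol = config$wham$tol,
                    min_count = config$wham$min_count)
  say("stage block errors")
  blocks <- block_error(series, edges, n_blocks = config$wham$n_blocks,
                        tol = config$wham$tol,
                        min_count = config$wham$min_count)
  pmf$error <- blocks$error
  bundle <- list(config = config, hash = hash, windows = windows,
                 series = series, pmf = pmf, blocks = blocks)
  if (spec$dim == 2) {
    say("stage path")
    graph <- grid_to_graph(pmf, connectivity = config$path$connectivity)
    se <- .pipeline_endpoints(config, spec, graph)
    path <- shortest_path(graph, from = se$from, to = se$to)
    profile <- profile_along_path(path)
    report <- locate_states(profile, smoothing = config$path$smoothing,
                            min_prominence = config$path$min_prominence)
    bundle$graph <- graph
    bundle$path <- path
    bundle$profile <- profile
    bundle$report <- report
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    say("stage write (", outdir, ")")
    writeLines(as.character(jsonlite::toJSON(
      c(list(hash = hash), unclass(config)), auto_unbox = TRUE,
      digits = NA, force = TRUE, pretty = TRUE)),
      file.path(outdir, "config.json"))
    allsamp <- do.call(rbind, lapply(series, function(x) {
      df <- data.frame(window_id = x$window_id,
                       step = seq_len(nrow(x$values)) * x$stride)
      for (j in seq_len(ncol(x$values)))
        df[[colnames(x$values)[j]]] <- x$values[, j]
      df
    }))
    .write_artifact(allsamp, file.path(outdir, "samples.tsv"),
                    meta = list(config = hash))
    write_pmf_grid(pmf, file.path(outdir, "pmf.tsv"))
    if (spec$dim == 2) {
      write_grid_path(bundle$path, file.path(outdir, "path.tsv"))
      .write_artifact(bundle$profile, file.path(outdir, "profile.tsv"),
                      meta = list(config = hash))
      .write_artifact(as.data.frame(bundle$report),
                      file.path(outdir, "report.tsv"),
                      meta = list(
                        config = hash,
                        barrier = attr(bundle$report, "barrier"),
                        reaction_energy = attr(bundle$report,
                                               "reaction_energy"),
                        reference = attr(bundle$report, "reference")))
    }
  }
  invisible(bundle)
}

# Map the landscape's reported minima to the nearest occupied bins; the
# reactant (path start) is the minimum with the smaller first coordinate.
.pipeline_endpoints <- function(config, spec, graph) {
  if (!is.null(config$path$start) && !is.null(config$path$end))
    return(list(from = config$path$start, to = config$path$end))
  rep <- landscape_report(spec)
  mins <- rep[rep$label == "min", , drop = FALSE]
  if (nrow(mins) < 2) stop("landscape report has fewer than two minima")
  mins <- mins[order(mins[[spec$axis_names[1]]]), , drop = FALSE]
  near <- function(px, py) {
    ix <- which.min(abs(graph$x - px)); iy <- which.min(abs(graph$y - py))
    if (graph$occupied[(ix - 1) * graph$dims[2] + iy])
      return(c(ix, iy))
    occ <- which(graph$occupied)
    oix <- (occ - 1) %/% graph$dims[2] + 1
    oiy <- (occ - 1) %% graph$dims[2] + 1
    k <- which.min((graph$x[oix] - px)^2 + (graph$y[oiy] - py)^2)
    c(oix[k], oiy[k])
  }
  list(from = near(mins[1, spec$axis_names[1]], mins[1, spec$axis_names[2]]),
       to = near(mins[2, spec$axis_names[1]], mins[2, spec$axis_names[2]]))
}

#' Bundled demonstration configuration (step-1-like surface)
#'
#' A desk-scale end-to-end configuration on the `psp_step1_like` landscape:
#' 2D umbrella windows on a 0.2 A grid over OPO in [-1.8, 1.4] and OHO in
#' [-1.0, 1.0], 1000 equilibration + 6000 production steps per window
#' (stride 10, so 600 records per window, divisible into three blocks),
#' 0.05 A WHAM bins (close to the production bias width, so the bin-centre
#' bias evaluation stays accurate), and a minimum-free-energy path between
#' the two basins.
#'
#' @param seed master seed.
#' @return A `run_config`.
#' @export
step1_demo_config <- function(seed = 1L) {
  run_config(
    landscape = landscape_spec("psp_step1_like"),
    ranges = list(c(-1.8, 1.4), c(-1.0, 1.0)),
    spacing = 0.2,
    sampler = list(n_equil = 1000L, n_prod = 6000L, stride = 10L),
    wham = list(bin_width = 0.05, tol = 1e-5, pad = 0.1),
    path = list(connectivity = 4, smoothing = 3, min_prominence = 1.0),
    seed = seed)
}
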