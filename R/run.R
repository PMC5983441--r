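#' Run a configured analysis
#'
#' Single entry point tying the modules together: builds the network
#' (built-in or from an edge-list file), applies edge deletions,
#' applies parameter overrides, executes one analysis block and writes
#' its outputs plus a provenance record (`provenance.json`: config
#' echo, seed, package and R versions, wall time) into the output
#' directory. Identical config and seed produce byte-identical CSV
#' outputs. On a mid-run failure partial outputs are removed and the
#' error re-raised.
#'
#' Config keys (a named list, or a JSON file path):
#' * `network` — `"ageing"` (default) or path to an edge-list TSV;
#' * `delete_edges` — character vector of `"source:target:sign"`;
#' * `params` — named overrides of `a`, `b`, `S`, `n`, `k`, `stress`, `gs`;
#' * `analysis` — one of `simulate`, `attractors`, `bifurcate`,
#'   `scan2d`, `landscape`, `saddle_path`;
#' * `settings` — analysis-specific arguments (see the corresponding
#'   function);
#' * `seed` — integer, recorded and used for every stochastic step;
#' * `out_dir` — output directory (created if needed).
#'
#' @param config named list or path to a JSON config file.
#' @return Invisibly, a list with the analysis result object and the
#'   paths written.
#' @export
run_grn <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  written <- character()
  result <- tryCatch(
    dispatch_analysis(config, record = function(f)
      written <<- c(written, f)),
    error = function(e) {
      unlink(written)
      stop("analysis failed (partial outputs removed): ",
           conditionMessage(e), call. = FALSE)
    })
  prov <- list(config = config,
               seed = config$seed,
               package_version = as.character(utils::packageVersion("ageingGRN")),
               r_version = R.version.string,
               wall_time_s = proc.time()[["elapsed"]] - t0,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(result = result,
                 files = c(written,
                           file.path(config$out_dir, "provenance.json"))))
}

config_defaults <- function() {
  list(network = "ageing", delete_edges = character(), params = list(),
       analysis = "attractors", settings = list(), seed = 1,
       out_dir = "grn-output")
}

validate_config <- function(config) {
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config <- utils::modifyList(defaults, config)
  analyses <- c("simulate", "attractors", "bifurcate", "scan2d",
                "landscape", "saddle_path")
  if (!config$analysis %in% analyses)
    stop("analysis must be one of: ", paste(analyses, collapse = ", "),
         call. = FALSE)
  if (!identical(config$network, "ageing") && !file.exists(config$network))
    stop("network file not found: ", config$network, call. = FALSE)
  config$seed <- as.integer(config$seed)
  config
}

config_network <- function(config) {
  net <- if (identical(config$network, "ageing")) ageing_network()
         else read_network_tsv(config$network)
  if (length(config$delete_edges))
    net <- delete_edges(net, unlist(config$delete_edges))
  net
}

config_params <- function(config) {
  p <- grn_params()
  ov <- config$params
  if (length(ov)) {
    nm <- names(ov)
    nm <- ifelse(tolower(nm) == "stress", "Stress",
          ifelse(tolower(nm) == "gs", "GS", nm))
    for (i in seq_along(ov)) p <- set_param(p, nm[i], as.numeric(ov[[i]]))
  }
  p
}

dispatch_analysis <- function(config, record) {
  net <- config_network(config)
  par <- config_params(config)
  s <- config$settings
  out <- function(name) file.path(config$out_dir, name)
  arg <- function(key, default) if (is.null(s[[key]])) default else s[[key]]

  switch(config$analysis,
    simulate = {
      x0 <- as.numeric(arg("x0", rep(0, length(net$nodes))))
      tr <- simulate_grn(net, par, x0, t_end = arg("t_end", 100),
                         n_out = arg("n_out", 201))
      f <- out("trajectory.csv")
      write_trajectory_csv(tr, f)
      record(f); record(paste0(f, ".meta.json"))
      tr
    },
    attractors = {
      att <- find_attractors(net, par,
                             n_starts = arg("n_starts", 1000),
                             x_max = arg("x_max", 3), seed = config$seed)
      f <- out("attractors.csv")
      write_attractors_csv(att, f); record(f)
      f2 <- out("fates.csv")
      utils::write.csv(fate_census(att), f2, row.names = FALSE)
      record(f2)
      att
    },
    bifurcate = {
      pname <- arg("param", "a")
      from <- arg("from", 0.3)
      p0 <- set_param(par, pname, from)
      x0 <- refine_fixed_point(
        converge_to_steady_state(net, p0,
                                 rep(0, length(net$nodes)))$state,
        net, p0)$state
      br <- continue_branch(net, par, pname, from, x0,
                            direction = arg("direction", 1),
                            step = arg("step", 0.01),
                            bounds = as.numeric(arg("bounds", c(0, 2.5))))
      f <- out("branch.csv")
      write_branch_csv(br, f)
      record(f); record(paste0(f, ".folds.json"))
      br
    },
    scan2d = {
      rm_ <- scan_two_parameters(net, par,
                                 a_values = as.numeric(arg("a_values",
                                     seq(0.3, 2, by = 0.1))),
                                 b_values = as.numeric(arg("b_values",
                                     c(0.05))),
                                 n_starts = arg("n_starts", 400),
                                 seed = config$seed)
      f <- out("region_map.csv")
      write_region_csv(rm_, f); record(f)
      rm_
    },
    landscape = {
      gr <- estimate_landscape(net, par,
                               coords = unlist(arg("coords", c("p53", "ATM"))),
                               n_traj = arg("n_traj", 10000),
                               t_end = arg("t_end", 50),
                               n_samples_per_traj = arg("n_samples_per_traj", 500),
                               n_boxes = arg("n_boxes", 100),
                               x_max = arg("x_max", 3), seed = config$seed)
      stem <- out("landscape")
      write_landscape(gr, stem)
      for (sfx in c(".counts.tsv", ".P.tsv", ".U.tsv", ".meta.json"))
        record(paste0(stem, sfx))
      basins <- basin_depth_rank(gr, locate_basins(gr))
      f <- out("basins.csv")
      utils::write.csv(basins, f, row.names = FALSE); record(f)
      list(landscape = gr, basins = basins)
    },
    saddle_path = {
      att <- find_attractors(net, par, n_starts = arg("n_starts", 200),
                             seed = config$seed)
      st <- which(att$stable)
      if (length(st) < 2)
        stop("need two attractors to trace a saddle path", call. = FALSE)
      i12 <- utils::head(st[order(att$basin_fraction[st],
                                  decreasing = TRUE)], 2)
      sad <- find_saddle(net, par, att$states[i12[1L], ],
                         att$states[i12[2L], ])
      paths <- saddle_path(net, par, sad$state,
                           coords = unlist(arg("coords", c("p53", "ATM"))))
      for (nmp in names(paths)) {
        f <- out(paste0("saddle_path_", nmp, ".csv"))
        utils::write.csv(paths[[nmp]], f, row.names = FALSE)
        record(f)
      }
      list(saddle = sad, paths = paths)
    })
}

#' Command-line interface
#'
#' Thin shell entry point over [run_grn()]. Subcommands map one-to-one
#' to analysis blocks: `simulate`, `attractors`, `bifurcate`, `scan2d`,
#' `landscape`, `perturb` (edge deletion applied before any analysis).
#' Options: `--config FILE` (JSON), `--seed INT`, `--out DIR`,
#' `--param key=value` (repeatable), `--delete source:target:sign`
#' (repeatable), plus `--set key=value` for analysis settings. An
#' executable wrapper script ships in `inst/cli/agegrn.R`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the live command line).
#' @return Invisibly, the [run_grn()] result.
#' @export
grn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: agegrn.R <subcommand> [options]",
    "",
    "subcommands: simulate | attractors | bifurcate | scan2d |",
    "             landscape | perturb (runs the analysis given by --analysis,",
    "             default attractors, on the edge-deleted network)",
    "",
    "options:",
    "  --config FILE              JSON config (keys: network, delete_edges,",
    "                             params, analysis, settings, seed, out_dir)",
    "  --seed INT                 RNG seed (default 1)",
    "  --out DIR                  output directory",
    "  --param key=value          parameter override (a,b,S,n,k,stress,gs);",
    "                             repeatable",
    "  --delete source:target:sign  delete an edge; repeatable",
    "  --set key=value            analysis setting override; repeatable",
    "  --analysis NAME            analysis for the perturb subcommand",
    "  --help                     this message",
    sep = "\n")
  if (length(args) == 0L || args[1L] %in% c("--help", "-h")) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  sub <- args[1L]
  args <- args[-1L]
  config <- config_defaults()
  if (sub != "perturb") config$analysis <- sub
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    val <- if (i < length(args)) args[i + 1L] else NA_character_
    switch(a,
      "--config" = {
        file_cfg <- jsonlite::read_json(val, simplifyVector = TRUE)
        config <- utils::modifyList(config, file_cfg)
        if (sub != "perturb") config$analysis <- sub
      },
      "--seed" = config$seed <- as.integer(val),
      "--out" = config$out_dir <- val,
      "--param" = {
        kv <- strsplit(val, "=", fixed = TRUE)[[1L]]
        config$params[[kv[1L]]] <- as.numeric(kv[2L])
      },
      "--delete" = config$delete_edges <- c(config$delete_edges, val),
      "--set" = {
        kv <- strsplit(val, "=", fixed = TRUE)[[1L]]
        v <- suppressWarnings(as.numeric(kv[2L]))
        config$settings[[kv[1L]]] <- if (is.na(v)) kv[2L] else v
      },
      "--analysis" = config$analysis <- val,
      "--help" = { cat(usage, "\n"); return(invisible(NULL)) },
      stop("unknown option: ", a, call. = FALSE))
    i <- i + 2L
  }
  res <- run_grn(config)
  message("outputs written to ", config$out_dir)
  invisible(res)
}
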