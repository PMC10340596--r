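## End-to-end orchestration: cohort (synthetic or CSV) -> complete-case
## filter -> classical statistics -> six stratum networks -> centrality +
## bootstrap -> clusters -> layouts -> machine- and human-readable report.
## A single global seed deterministically derives the per-stage seeds
## (cv = seed + 1, bootstrap = seed + 2, layout = seed + 3) so one value
## reproduces an entire run byte for byte.

#' Default pipeline configuration
#'
#' @return Nested list of defaults: `mode` ("synthetic" or "csv"),
#'   `input_csv`, `seed`, `outdir`, `synthetic` (passed to
#'   [synthetic_spec()]: `n_dyads`, `dyad_rho`, `time_rho`, `n_dropout`,
#'   `planted_pcor`, `sex_effect`), `mgm` (`folds`, `n_lambda`,
#'   `lambda_min_ratio`, `select`, `rule`, `min_n`), `bootstrap` (`B`),
#'   `layout` (`iterations`).
#' @export
default_config <- function() {
  list(
    mode = "synthetic",
    input_csv = NULL,
    seed = 101L,
    outdir = NULL,
    synthetic = list(n_dyads = 23L, dyad_rho = 0.3, time_rho = 0.4,
                     n_dropout = 7L, planted_pcor = 0.3,
                     sex_effect = c(Somatisation = 0.5, Contentedness = 0.5)),
    mgm = list(folds = 10L, n_lambda = 50L, lambda_min_ratio = 1e-3,
               select = "1se", rule = "and", min_n = 10L),
    bootstrap = list(B = 200L),
    layout = list(iterations = 500L)
  )
}

check_enum <- function(value, allowed, key) {
  if (!value %in% allowed) {
    stop("config key '", key, "': value '", value,
         "' not allowed; must be one of: ", paste(allowed, collapse = ", "))
  }
}

check_positive_int <- function(value, key, minimum = 1) {
  if (!is.numeric(value) || length(value) != 1 || is.na(value) ||
      value != round(value) || value < minimum) {
    stop("config key '", key, "': must be an integer >= ", minimum)
  }
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys (naming them), and checks value
#' ranges.
#'
#' @param config A partial configuration list, or the path of a YAML/JSON
#'   file holding one.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (!is.null(config$synthetic$sex_effect)) {
      config$synthetic$sex_effect <- unlist(config$synthetic$sex_effect)
    }
  }
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (blk in c("synthetic", "mgm", "bootstrap", "layout")) {
    unknown <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(unknown) > 0) {
      stop("unknown config key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "))
    }
  }
  cfg <- modifyList(defaults, config)
  check_enum(cfg$mode, c("synthetic", "csv"), "mode")
  check_enum(cfg$mgm$select, c("1se", "min"), "mgm$select")
  check_enum(cfg$mgm$rule, c("and", "or"), "mgm$rule")
  check_positive_int(cfg$mgm$folds, "folds", minimum = 2)
  check_positive_int(cfg$mgm$n_lambda, "mgm$n_lambda", minimum = 2)
  check_positive_int(cfg$mgm$min_n, "mgm$min_n", minimum = 1)
  check_positive_int(cfg$bootstrap$B, "bootstrap$B", minimum = 0)
  check_positive_int(cfg$layout$iterations, "layout$iterations")
  check_positive_int(cfg$seed, "seed", minimum = 0)
  check_positive_int(cfg$synthetic$n_dyads, "synthetic$n_dyads")
  check_positive_int(cfg$synthetic$n_dropout, "synthetic$n_dropout",
                     minimum = 0)
  if (cfg$synthetic$n_dropout > cfg$synthetic$n_dyads) {
    stop("config key 'synthetic$n_dropout': cannot exceed n_dyads")
  }
  if (cfg$mode == "csv" && is.null(cfg$input_csv)) {
    stop("config key 'input_csv': required when mode = \"csv\"")
  }
  cfg
}

synthetic_spec_from_config <- function(cfg) {
  sc <- cfg$synthetic
  n_dropout <- sc$n_dropout
  dropout <- if (n_dropout > 0) {
    seq(sc$n_dyads - n_dropout + 1, sc$n_dyads)
  } else integer(0)
  synthetic_spec(
    n_dyads = sc$n_dyads,
    precision = lapply(default_planted_edges(sc$planted_pcor),
                       build_precision),
    sex_effect = sc$sex_effect,
    dyad_rho = sc$dyad_rho, time_rho = sc$time_rho,
    dropout = dropout,
    seed = cfg$seed)
}

log_stage <- function(quiet, ...) {
  if (!quiet) message("[distressnet] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: cohort generation or ingestion,
#' complete-case filtering, classical statistics, one mixed graphical
#' model per role x time stratum (six for a complete two-role three-time
#' cohort), node predictability, centrality with bootstrap stability,
#' walktrap clustering, and an average layout shared by all networks.
#' Deterministic given the config seed. When `outdir` is set, writes the
#' cohort CSV, per-stratum GraphML + edge/node CSVs, `metrics.csv`,
#' `predictability.csv`, `clusters.csv`, `layout.csv`, `report.json` and
#' `report.md`.
#'
#' @param config Configuration (list or file path), see
#'   [validate_config()].
#' @param quiet Suppress stage log messages.
#' @return A `run_report` list: `status` (`"ok"` or
#'   `"no_complete_dyads"`), cohort counts, per-stratum summaries, the
#'   networks and derived tables.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- validate_config(config)
  seeds <- list(global = cfg$seed, cv = cfg$seed + 1L,
                bootstrap = cfg$seed + 2L, layout = cfg$seed + 3L)

  log_stage(quiet, "stage: cohort (mode = ", cfg$mode, ")")
  truth <- NULL
  if (cfg$mode == "synthetic") {
    gen <- generate_cohort(synthetic_spec_from_config(cfg))
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    cohort <- read_cohort(cfg$input_csv)
  }

  log_stage(quiet, "stage: complete-case filter")
  cc <- complete_case_filter(cohort)

  report <- list(
    package_version = as.character(packageVersion("distressnet")),
    seeds = seeds,
    config = cfg,
    cohort = cc$report
  )

  if (cc$report$n_complete == 0) {
    report$status <- "no_complete_dyads"
    report$networks <- list()
    log_stage(quiet, "no complete dyads; stopping after the filter stage")
    if (!is.null(cfg$outdir)) write_run_artifacts(report, NULL, cfg, quiet)
    return(structure(report, class = "run_report"))
  }

  log_stage(quiet, "stage: classical statistics")
  stats_tab <- cohort_stats(cc$cohort)

  log_stage(quiet, "stage: stratification")
  strata <- stratify(cc$cohort)

  log_stage(quiet, "stage: network estimation + bootstrap (B = ",
            cfg$bootstrap$B, ")")
  mgm_cfg <- c(cfg$mgm, list(seed = seeds$cv))
  nets <- list()
  fits <- list()
  boots <- list()
  for (k in names(strata)) {
    if (cfg$bootstrap$B > 0) {
      bs <- bootstrap_centrality(strata[[k]], mgm_cfg, B = cfg$bootstrap$B,
                                 seed = seeds$bootstrap)
      net <- bs$network
      net$edge_support <- bs$edge_support
      nets[[k]] <- net
      fits[[k]] <- bs$fits
      boots[[k]] <- bs
    } else {
      est <- estimate_stratum_network(strata[[k]], mgm_cfg)
      nets[[k]] <- est$network
      fits[[k]] <- est$fits
      boots[[k]] <- NULL
    }
  }

  log_stage(quiet, "stage: predictability, clusters, layouts")
  pred <- lapply(names(strata), function(k)
    cbind(stratum = k, predictability(fits[[k]], strata[[k]], nets[[k]])))
  names(pred) <- names(strata)
  clusters <- lapply(nets, walktrap_cluster)
  layout <- average_layout(nets, seed = seeds$layout,
                           iterations = cfg$layout$iterations)
  centrality <- centrality_table(nets)

  ## node sizes: per role and time, mean subscale score relative to T1
  sizes <- list()
  for (role in parent_roles()) {
    t1_means <- colMeans(strata[[paste0(role, "_T1")]]$data[, sq_subscales(),
                                                            drop = FALSE])
    for (tp in time_points()) {
      k <- paste(role, tp, sep = "_")
      tk_means <- colMeans(strata[[k]]$data[, sq_subscales(), drop = FALSE])
      sz <- try(node_size_scale(tk_means, t1_means), silent = TRUE)
      if (inherits(sz, "try-error")) {
        sz <- setNames(rep(1, length(sq_subscales())), sq_subscales())
      }
      sizes[[k]] <- c(sz, child_sex = 1)
    }
  }

  report$status <- "ok"
  report$stats <- stats_tab
  report$strata_n <- vapply(strata, function(s) s$n, integer(1))
  report$networks <- lapply(nets, function(nt) {
    el <- network_edge_list(nt)
    list(stratum = paste(nt$parent_role, nt$time_point, sep = "_"),
         n = nt$n, n_edges = nrow(el),
         n_unstable = nrow(nt$unstable))
  })
  report$clusters <- lapply(clusters, function(cl)
    list(n_communities = cl$n_communities, modularity = cl$modularity,
         membership = as.list(cl$membership)))
  report$bootstrap <- if (cfg$bootstrap$B > 0) {
    lapply(boots, function(b) list(B = b$B, B_failed = b$B_failed))
  } else NULL

  result <- structure(report, class = "run_report")
  attr(result, "objects") <- list(
    cohort = cc$cohort, truth = truth, strata = strata, networks = nets,
    fits = fits, bootstrap = boots, predictability = pred,
    clusters = clusters, layout = layout, centrality = centrality,
    node_sizes = sizes, stats = stats_tab)
  if (!is.null(cfg$outdir)) {
    write_run_artifacts(result, attr(result, "objects"), cfg, quiet)
  }
  result
}

write_run_artifacts <- function(report, objects, cfg, quiet = FALSE) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$outdir, ...)
  log_stage(quiet, "writing artifacts to ", cfg$outdir)
  json <- report
  attr(json, "objects") <- NULL
  class(json) <- "list"
  json$config$outdir <- NULL   # I/O location, not an analysis parameter
  jsonlite::write_json(json, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(render_report_md(report), out("report.md"))
  if (is.null(objects)) return(invisible(NULL))
  write_cohort(objects$cohort, out("cohort.csv"))
  for (k in names(objects$networks)) {
    export_network(objects$networks[[k]], out(k),
                   node_size = objects$node_sizes[[k]])
  }
  write.csv(objects$centrality, out("metrics.csv"), row.names = FALSE)
  write.csv(do.call(rbind, objects$predictability), out("predictability.csv"),
            row.names = FALSE)
  cl <- do.call(rbind, lapply(names(objects$clusters), function(k) {
    m <- objects$clusters[[k]]$membership
    data.frame(stratum = k, node = names(m), community = as.integer(m),
               modularity = objects$clusters[[k]]$modularity)
  }))
  write.csv(cl, out("clusters.csv"), row.names = FALSE)
  write.csv(objects$layout$coords, out("layout.csv"), row.names = FALSE)
  if (length(objects$bootstrap) > 0 && !is.null(objects$bootstrap[[1]])) {
    bs <- do.call(rbind, lapply(names(objects$bootstrap), function(k)
      cbind(stratum = k, objects$bootstrap[[k]]$summary)))
    write.csv(bs, out("bootstrap.csv"), row.names = FALSE)
  }
  invisible(NULL)
}

render_report_md <- function(report) {
  lines <- c(
    "# distressnet run report",
    "",
    paste0("- package version: ", report$package_version),
    paste0("- status: ", report$status),
    paste0("- seeds: global ", report$seeds$global, ", cv ",
           report$seeds$cv, ", bootstrap ", report$seeds$bootstrap,
           ", layout ", report$seeds$layout),
    "",
    "## Cohort",
    paste0("- enrolled dyads: ", report$cohort$n_enrolled),
    paste0("- complete-case dyads: ", report$cohort$n_complete),
    paste0("- dropped dyads: ", report$cohort$n_dropped))
  if (!is.null(report$networks) && length(report$networks) > 0) {
    lines <- c(lines, "", "## Networks",
               vapply(report$networks, function(nw)
                 paste0("- ", nw$stratum, ": n = ", nw$n, ", ",
                        nw$n_edges, " edges (", nw$n_unstable,
                        " sign-unstable pairs dropped)"), character(1)))
  }
  if (!is.null(report$clusters)) {
    lines <- c(lines, "", "## Clusters",
               vapply(names(report$clusters), function(k)
                 paste0("- ", k, ": ", report$clusters[[k]]$n_communities,
                        " communities, Q = ",
                        format(report$clusters[[k]]$modularity,
                               digits = 4)), character(1)))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
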