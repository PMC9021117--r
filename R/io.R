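# File formats and the reproducible end-to-end pipeline.

#' Read a multivariate time series from CSV
#'
#' Wide layout: one row per measurement occasion, a time column plus one
#' column per variable. Long layout: `(time, variable, value)` triplets,
#' pivoted to wide. Rows are sorted by time; duplicated timestamps are an
#' error (the offending time is named). Non-numeric cells become missing
#' values and their count is reported via a message.
#'
#' @param path CSV file path.
#' @param time_col name of the time column (default `"time"`).
#' @param var_cols variable columns to keep; default: all non-time columns
#'   (wide) or all variables present (long).
#' @param layout `"wide"` (default) or `"long"`.
#' @param var_col,value_col column names for the long layout.
#' @return an [irregular_ts()].
#' @export
read_timeseries_csv <- function(path, time_col = "time", var_cols = NULL,
                                layout = c("wide", "long"),
                                var_col = "variable", value_col = "value") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!time_col %in% names(df))
    stop("time column '", time_col, "' not found in ", path)
  if (layout == "long") {
    for (cn in c(var_col, value_col))
      if (!cn %in% names(df)) stop("column '", cn, "' not found in ", path)
    vars <- if (is.null(var_cols)) unique(df[[var_col]]) else var_cols
    times <- sort(unique(as.numeric(df[[time_col]])))
    M <- matrix(NA_real_, length(times), length(vars),
                dimnames = list(NULL, vars))
    n_bad <- 0L
    val <- suppressWarnings(as.numeric(df[[value_col]]))
    n_bad <- sum(is.na(val) & !is.na(df[[value_col]]) &
                   df[[value_col]] != "NA" & df[[value_col]] != "")
    ti <- match(as.numeric(df[[time_col]]), times)
    vi <- match(df[[var_col]], vars)
    keep <- !is.na(vi)
    if (anyDuplicated(cbind(ti, vi)[keep, , drop = FALSE]))
      stop("duplicated (time, variable) entries in long-layout file")
    M[cbind(ti[keep], vi[keep])] <- val[keep]
    if (n_bad > 0) message(n_bad, " non-numeric cell(s) treated as missing")
    return(irregular_ts(times, M, vars))
  }
  vars <- if (is.null(var_cols)) setdiff(names(df), time_col) else var_cols
  miss <- setdiff(vars, names(df))
  if (length(miss))
    stop("variable column(s) not found: ", paste(miss, collapse = ", "))
  times <- as.numeric(df[[time_col]])
  ord <- order(times)
  times <- times[ord]
  dup <- which(diff(times) == 0)
  if (length(dup))
    stop("duplicated timestamp(s): ",
         paste(unique(format(times[dup])), collapse = ", "))
  raw <- df[ord, vars, drop = FALSE]
  M <- matrix(NA_real_, nrow(raw), length(vars),
              dimnames = list(NULL, vars))
  n_bad <- 0L
  for (j in seq_along(vars)) {
    v <- suppressWarnings(as.numeric(as.character(raw[[j]])))
    n_bad <- n_bad + sum(is.na(v) & !is.na(raw[[j]]) &
                           raw[[j]] != "NA" & raw[[j]] != "")
    M[, j] <- v
  }
  if (n_bad > 0) message(n_bad, " non-numeric cell(s) treated as missing")
  irregular_ts(times, M, vars)
}

#' Write a time series to wide CSV
#'
#' @param x an [irregular_ts()].
#' @param path output path.
#' @param time_col name for the time column.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path, time_col = "time") {
  stopifnot(inherits(x, "irts"))
  df <- data.frame(time = x$times, as.data.frame(x$values),
                   check.names = FALSE)
  names(df)[1] <- time_col
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a model as a network file
#'
#' Writes the weighted directed graph of a CT model (edges = nonzero drift
#' entries: the weighted local dependence graph) or a DT model (edges =
#' nonzero lagged parameters). The edge-list CSV has columns
#' `from, to, weight, type` with `type` in `auto`/`cross`; zero-weight
#' edges are omitted. GraphML output carries node labels, edge weights and
#' a `model_kind` graph attribute (`"CT"` or `"DT"`) so renderers can
#' distinguish the two conventions.
#'
#' @param model a `"ctmodel"` or `"dtmodel"`.
#' @param path output path.
#' @param format `"edgelist_csv"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(model, path,
                           format = c("edgelist_csv", "graphml")) {
  format <- match.arg(format)
  if (inherits(model, "ctmodel")) {
    W <- model$drift; kind <- "CT"
  } else if (inherits(model, "dtmodel")) {
    W <- model$lagged; kind <- "DT"
  } else stop("'model' must be a ctmodel or dtmodel")
  labels <- colnames(W)
  idx <- which(W != 0, arr.ind = TRUE)
  edges <- data.frame(
    from = labels[idx[, 2]],
    to = labels[idx[, 1]],
    weight = W[idx],
    type = ifelse(idx[, 1] == idx[, 2], "auto", "cross"),
    stringsAsFactors = FALSE)
  if (format == "edgelist_csv") {
    utils::write.csv(edges, path, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "weight", "type")],
      directed = TRUE,
      vertices = data.frame(name = labels, stringsAsFactors = FALSE))
    g <- igraph::set_graph_attr(g, "model_kind", kind)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Reconstruct a weight matrix from an exported edge list
#'
#' Inverse of [export_network()] for the edge-list format: entries absent
#' from the file are zero.
#'
#' @param path edge-list CSV written by [export_network()].
#' @param labels optional variable ordering; default: order of appearance.
#' @return labeled square weight matrix.
#' @export
read_network_csv <- function(path, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(labels)) labels <- unique(c(df$from, df$to))
  p <- length(labels)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  W[cbind(match(df$to, labels), match(df$from, labels))] <- df$weight
  W
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Reproducible end-to-end run mirroring a typical analysis: obtain data
#' (from file or by simulation), fit the CT-VAR (and the DT-VAR baseline),
#' derive lagged-parameter curves, centrality curves, optional effect
#' curves and intervention trajectories, and write everything as tidy CSV
#' plus a JSON fit and manifest. The same config and seed reproduce all
#' outputs exactly.
#'
#' The config is a list (or path to a JSON file) with elements:
#' \describe{
#'   \item{seed}{integer seed for all randomness.}
#'   \item{time_unit}{declared time unit, default `"hours"`; echoed in the
#'     manifest -- drift rates are meaningless without it.}
#'   \item{data}{either `list(file=, time_col=, vars=, layout=)` or
#'     `list(simulate = list(model =, days =, beeps =, window =))` where
#'     `model` is a model JSON path or the name of an [example_models()]
#'     entry.}
#'   \item{fit}{`list(method = "ct"|"dt"|"both", n_starts =)`.}
#'   \item{grid}{`list(tmax =, step =)`, default 0..5 by 0.05.}
#'   \item{measures}{centrality measures to tabulate; default
#'     `c("TEC", "IEC", "EI1", "EI2", "BC")`.}
#'   \item{effects}{optional list of
#'     `list(kind =, cause =, effect =, mediators =)`.}
#'   \item{ci_draws}{optional: draws for uncertainty bands on the lagged
#'     curves (0 disables).}
#' }
#'
#' @param config list or path to a JSON config.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  time_unit <- if (is.null(config$time_unit)) "hours" else config$time_unit
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  set.seed(seed)

  data <- pipeline_stage("data", {
    dc <- config$data
    if (is.null(dc)) stop("config$data is required")
    if (!is.null(dc$simulate)) {
      sc <- dc$simulate
      model <- if (is.character(sc$model) && file.exists(sc$model))
        read_model(sc$model)
      else if (is.character(sc$model) && sc$model %in% names(example_models()))
        example_models()[[sc$model]]
      else stop("unknown simulation model: ", sc$model)
      times <- esm_schedule(
        n_days = if (is.null(sc$days)) 60 else sc$days,
        beeps_per_day = if (is.null(sc$beeps)) 6 else sc$beeps,
        waking_window_hours = if (is.null(sc$window)) 13.5 else sc$window)
      note("simulated ", length(times), " observations from model '",
           sc$model, "'")
      sample_ou_path(model, times)
    } else {
      d <- read_timeseries_csv(dc$file,
        time_col = if (is.null(dc$time_col)) "time" else dc$time_col,
        var_cols = dc$vars,
        layout = if (is.null(dc$layout)) "wide" else dc$layout)
      note("read ", length(d$times), " observations from ", dc$file)
      d
    }
  })

  # jsonlite may simplify a list of effect specs to a data frame
  effects_cfg <- config$effects
  if (is.data.frame(effects_cfg))
    effects_cfg <- lapply(seq_len(nrow(effects_cfg)),
                          function(i) as.list(effects_cfg[i, ]))
  config$effects <- effects_cfg

  # validate any variable names referenced by the config before computing
  pipeline_stage("validate", {
    for (ef in config$effects) {
      resolve_nodes(ef$cause, data$labels, "cause")
      resolve_nodes(ef$effect, data$labels, "effect")
      resolve_nodes(ef$mediators, data$labels, "mediators",
                    allow_empty = TRUE)
    }
  })

  gc_ <- config$grid
  tmax <- if (is.null(gc_$tmax)) 5 else gc_$tmax
  step <- if (is.null(gc_$step)) 0.05 else gc_$step
  grid <- seq(0, tmax, by = step)
  method <- if (is.null(config$fit$method)) "both" else config$fit$method
  n_starts <- if (is.null(config$fit$n_starts)) 10 else config$fit$n_starts

  outputs <- character(0)
  add_out <- function(f) outputs <<- c(outputs, basename(f))

  ctfit <- dtfit <- NULL
  if (method %in% c("ct", "both")) {
    ctfit <- pipeline_stage("fit_ct",
      fit_ct_var(data, n_starts = n_starts, seed = seed))
    note("CT fit: logLik = ", format(ctfit$loglik), ", converged = ",
         ctfit$converged)
  }
  if (method %in% c("dt", "both")) {
    dtfit <- pipeline_stage("fit_dt", fit_dt_var(data))
    note("DT fit: reference interval = ", format(dtfit$model$interval))
  }
  pipeline_stage("write_fit", {
    fit_obj <- list(seed = seed, time_unit = time_unit)
    if (!is.null(ctfit))
      fit_obj$ct <- list(
        labels = data$labels,
        drift = unname(ctfit$model$drift),
        diffusion = unname(ctfit$model$diffusion),
        equilibrium = unname(ctfit$model$equilibrium),
        loglik = ctfit$loglik, converged = ctfit$converged,
        n_pairs = ctfit$n_pairs)
    if (!is.null(dtfit))
      fit_obj$dt <- list(
        labels = data$labels,
        lagged = unname(dtfit$model$lagged),
        interval = dtfit$model$interval,
        residual_cov = unname(dtfit$model$residual_cov),
        loglik = dtfit$loglik, n_pairs = dtfit$n_pairs)
    jsonlite::write_json(fit_obj, file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    add_out("fit.json")
  })

  if (!is.null(ctfit)) {
    model <- ctfit$model
    pipeline_stage("phi_curve", {
      pc <- phi_curve(model, grid)
      utils::write.csv(as.data.frame(pc),
                       file.path(out_dir, "phi_curve.csv"),
                       row.names = FALSE)
      add_out("phi_curve.csv")
    })
    pipeline_stage("centrality", {
      measures <- config$measures
      if (is.null(measures)) measures <- c("TEC", "IEC", "EI1", "EI2", "BC")
      rows <- lapply(measures, function(m) {
        cc <- if (m %in% c("TEC", "IEC")) centrality_curve(model, m, grid)
              else dt_centrality_curve(model, m, grid)
        as.data.frame(cc)
      })
      utils::write.csv(do.call(rbind, rows),
                       file.path(out_dir, "centrality.csv"),
                       row.names = FALSE)
      add_out("centrality.csv")
    })
    if (length(config$effects)) pipeline_stage("effects", {
      rows <- lapply(config$effects, function(ef)
        as.data.frame(effect_curve(model,
          kind = if (is.null(ef$kind)) "total" else ef$kind,
          cause = ef$cause, effect = ef$effect,
          mediators = ef$mediators, grid = grid)))
      utils::write.csv(do.call(rbind, rows),
                       file.path(out_dir, "effects.csv"),
                       row.names = FALSE)
      add_out("effects.csv")
    })
    pipeline_stage("network", {
      export_network(model, file.path(out_dir, "network.csv"))
      add_out("network.csv")
    })
  }

  manifest <- list(
    seed = seed, time_unit = time_unit,
    config_hash = digest_config(config),
    n_obs = length(data$times), labels = data$labels,
    outputs = outputs,
    package_version = as.character(utils::packageVersion("ctdyn")),
    complete = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(manifest)
}

# Small stable hash of the config (sum of char codes of its serialization;
# enough to detect config changes in the manifest without new deps).
digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(s)) %% 251)) %% .Machine$integer.max)
}
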