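.vocanet_csv_header <- c("jitter", "f0", "f1f2", "intensity", "speech_rate",
                         "anxiety", "group")

#' Read a feature-table CSV
#'
#' Expects the standard header `jitter, f0, f1f2, intensity, speech_rate,
#' anxiety, group` (order-insensitive; unknown extra columns are ignored
#' with a warning). Numeric parsing is locale-independent; empty cells
#' become `NA`. Anxiety ratings outside `{0,1,2,3}` (NA allowed) fail with
#' the offending row.
#'
#' @param path CSV path.
#' @return data.frame in canonical column order.
#' @export
read_feature_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = NA, na.strings = c("", "NA"))
  missing <- setdiff(.vocanet_csv_header, names(x))
  if (length(missing) > 0)
    stop("feature CSV ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(x), .vocanet_csv_header)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  x <- x[, .vocanet_csv_header]
  for (v in setdiff(.vocanet_csv_header, "group")) {
    if (!is.numeric(x[[v]])) {
      bad <- which(!is.na(x[[v]]) & is.na(suppressWarnings(as.numeric(x[[v]]))))
      if (length(bad) > 0)
        stop("non-numeric value in column ", v, ", row ", bad[1], ": ",
             x[[v]][bad[1]])
      x[[v]] <- as.numeric(x[[v]])
    }
  }
  bad <- which(!is.na(x$anxiety) & !x$anxiety %in% 0:3)
  if (length(bad) > 0)
    stop("anxiety rating out of range (0-3) in row ", bad[1], ": ",
         x$anxiety[bad[1]])
  x
}

#' Write a feature-table CSV
#'
#' @param table data.frame with the standard columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  stopifnot(all(.vocanet_csv_header %in% names(table)))
  utils::write.csv(table[, .vocanet_csv_header], path, row.names = FALSE)
  invisible(path)
}

#' Export / import a network model as JSON
#'
#' @param model a `network_model`.
#' @param path output path.
#' @return `path` invisibly (`write_network_json`); a `network_model`
#'   (`read_network_json`).
#' @export
write_network_json <- function(model, path) {
  stopifnot(inherits(model, "network_model"))
  obj <- list(labels = model$labels,
              weights = unname(apply(model$weights, 1, as.numeric,
                                     simplify = FALSE)),
              lambda_selected = model$lambda_selected,
              gamma = model$gamma, n = model$n,
              ebic_path = model$ebic_path)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.matrix(obj$weights)) obj$weights else
    do.call(rbind, lapply(obj$weights, as.numeric))
  dimnames(W) <- list(obj$labels, obj$labels)
  structure(list(labels = obj$labels, weights = W, precision = NULL,
                 lambda_selected = obj$lambda_selected, gamma = obj$gamma,
                 ebic_path = as.data.frame(obj$ebic_path), n = obj$n),
            class = "network_model")
}

#' Pipeline run configuration
#'
#' Builds a validated configuration for [run_pipeline()] from a YAML file
#' or a list. Every stochastic stage has its own seed, derived from
#' `seed` when not given explicitly, so partial re-runs are reproducible
#' stage by stage.
#'
#' @param x path to a YAML file, or a named list of settings.
#' @return a `run_config` list with elements `input` (list: `mode` one of
#'   `"synthetic"`, `"features_csv"`, `"audio_dir"` plus mode-specific
#'   fields), `network` (gamma, n_lambdas, lambda_min_ratio, B, P),
#'   `extraction` (an [extract_config()]), and `seeds`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  seed <- if (is.null(x$seed)) 1L else as.integer(x$seed)
  cfg <- list(
    input = modifyList(list(mode = "synthetic", features_csv = NULL,
                            audio_dir = NULL, annotations = NULL),
                       if (is.null(x$input)) list() else x$input),
    network = modifyList(list(gamma = 0.5, n_lambdas = 100,
                              lambda_min_ratio = 0.01, B = 200, P = 200),
                         if (is.null(x$network)) list() else x$network),
    extraction = do.call(extract_config,
                         if (is.null(x$extraction)) list() else x$extraction),
    seed = seed,
    seeds = modifyList(list(synth = seed + 11L, bootstrap = seed + 23L,
                            cs = seed + 37L, nct = seed + 51L,
                            layout = seed + 67L),
                       if (is.null(x$seeds)) list() else x$seeds))
  if (!cfg$input$mode %in% c("synthetic", "features_csv", "audio_dir"))
    stop("unknown input mode: ", cfg$input$mode)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Produces, under `out_dir`: `features.csv`, `table1.json` (group
#' descriptives), `network_total.json`, `network_low.json`,
#' `network_high.json`, `redundancy.csv` (goldbricker screen),
#' `layout_total.csv` (seeded force-directed coordinates),
#' `stability_low.json` / `stability_high.json` (bootstrap CIs and CS
#' coefficients), `nct.json`, and `run_log.txt`.
#' Identical config and seeds give byte-identical JSON outputs.
#'
#' @param config a [run_config()] (or list/path coerced through it).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run_log.txt")
  log <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat(sprintf("vocanet %s | R %s | base seed %d\n",
              as.character(utils::packageVersion("vocanet")),
              paste(R.version$major, R.version$minor, sep = "."),
              config$seed), file = logf)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tab <- stage("input", switch(config$input$mode,
    synthetic = {
      specs <- study_group_specs()
      rbind(generate_feature_table(specs$low, seed = config$seeds$synth),
            generate_feature_table(specs$high, seed = config$seeds$synth + 1L))
    },
    features_csv = read_feature_csv(config$input$features_csv),
    audio_dir = .extract_audio_dir(config)))
  write_feature_csv(tab, file.path(out_dir, "features.csv"))
  log("input: ", nrow(tab), " rows (mode ", config$input$mode, ")")

  p <- length(intersect(.vocanet_speech_vars, names(tab)))
  if (nrow(tab) < 3 * (p + 1))
    stop("pipeline stage 'network' refused: n = ", nrow(tab),
         " rows is too small for network estimation (need >= ",
         3 * (p + 1), ")")

  t1 <- stage("table1", group_summary(tab))
  jsonlite::write_json(t1, file.path(out_dir, "table1.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  gr <- split_groups(tab)
  nets <- stage("network", list(
    total = estimate_network(tab, gamma = config$network$gamma),
    low = estimate_network(gr$low, columns = .vocanet_speech_vars,
                           gamma = config$network$gamma),
    high = estimate_network(gr$high, columns = .vocanet_speech_vars,
                            gamma = config$network$gamma)))
  for (nm in names(nets))
    write_network_json(nets[[nm]],
                       file.path(out_dir, paste0("network_", nm, ".json")))
  log("networks: total/low/high estimated (gamma ", config$network$gamma, ")")

  # redundancy screen and total-network layout
  red <- stage("redundancy", goldbricker(tab, columns = .vocanet_speech_vars))
  utils::write.csv(red, file.path(out_dir, "redundancy.csv"),
                   row.names = FALSE)
  xy <- fr_layout(nets$total, seed = config$seeds$layout)
  utils::write.csv(data.frame(node = rownames(xy), x = xy[, 1], y = xy[, 2]),
                   file.path(out_dir, "layout_total.csv"), row.names = FALSE)
  log("redundancy screen: ", sum(red$redundant), " pair(s) flagged")

  B <- config$network$B
  for (nm in c("low", "high")) {
    bs <- stage(paste0("stability_", nm),
                bootstrap_edges(gr[[nm]], columns = .vocanet_speech_vars,
                                B = B, seed = config$seeds$bootstrap,
                                gamma = config$network$gamma,
                                warn_small = FALSE))
    cs <- stage(paste0("cs_", nm),
                cs_coefficient(gr[[nm]], columns = .vocanet_speech_vars,
                               B = B, seed = config$seeds$cs,
                               gamma = config$network$gamma))
    jsonlite::write_json(
      list(edge_ci = bs$edge_ci, ei_ci = bs$ei_ci,
           cs_coefficient = cs$cs_coefficient, cs_curve = cs$cs_curve,
           stability_flag = cs$stability_flag, B = B,
           seed_bootstrap = bs$seed, seed_cs = cs$seed),
      file.path(out_dir, paste0("stability_", nm, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    log("stability (", nm, "): CS = ", cs$cs_coefficient)
  }

  cmp <- stage("nct", nct(gr$high, gr$low, P = config$network$P,
                          seed = config$seeds$nct,
                          gamma = config$network$gamma))
  jsonlite::write_json(
    list(global = cmp$global, max_edge = cmp$max_edge, edges = cmp$edges,
         nodes = cmp$nodes, P = cmp$P, seed = cmp$seed),
    file.path(out_dir, "nct.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  log("nct: S = ", cmp$global$S, ", p = ", cmp$global$p)
  invisible(out_dir)
}

# extract features for every WAV in a directory; annotations (transcripts
# or sidecar JSON) are matched by file stem
.extract_audio_dir <- function(config) {
  dir <- config$input$audio_dir
  wavs <- list.files(dir, pattern = "\\.wav$", full.names = TRUE)
  if (length(wavs) == 0) stop("no WAV files in ", dir)
  rows <- lapply(wavs, function(w) {
    stem <- sub("\\.wav$", "", w)
    ann <- NULL
    if (file.exists(paste0(stem, ".txt"))) {
      ann <- paste(readLines(paste0(stem, ".txt"), warn = FALSE),
                   collapse = " ")
    } else if (file.exists(paste0(stem, ".json"))) {
      ann <- jsonlite::read_json(paste0(stem, ".json"),
                                 simplifyVector = TRUE)
    }
    sig <- read_wav(w)
    fr <- extract_features(sig, config$extraction, annotation = ann)
    fr$anxiety <- NA_integer_
    fr$group <- NA_character_
    fr
  })
  tab <- do.call(rbind, rows)
  ratings <- config$input$annotations
  if (!is.null(ratings)) {
    r <- read.csv(ratings, stringsAsFactors = FALSE)
    stem <- sub("\\.wav$", "", basename(wavs))
    m <- match(stem, r$file)
    tab$anxiety <- r$anxiety[m]
    tab$group <- ifelse(tab$anxiety <= 1, "low", "high")
  }
  tab
}
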