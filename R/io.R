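#' Read a rate matrix from CSV or JSON
#'
#' CSV: a dense square table with a header row of state labels (first
#' column optionally the row labels). JSON: an object
#' `{"labels": [...], "rates": [[...]]}`. In both cases the diagonal is
#' refilled to satisfy the zero-row-sum condition.
#'
#' @param path file path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return a [rate_matrix()].
#' @export
read_rate_matrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::fromJSON(path)
    if (is.null(obj$rates)) stop("JSON rate matrix needs a 'rates' field")
    m <- as.matrix(obj$rates)
    labels <- if (!is.null(obj$labels)) as.character(obj$labels) else NULL
    return(rate_matrix(m, labels = labels))
  }
  if (ext == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] %in% c("", "X", "state") || !is.numeric(df[[1]])) {
      rn <- df[[1]]
      df <- df[, -1, drop = FALSE]
      m <- as.matrix(df)
      rownames(m) <- rn
    } else {
      m <- as.matrix(df)
    }
    return(rate_matrix(m, labels = colnames(m)))
  }
  stop("unsupported rate-matrix format: .", ext)
}

#' Write a rate matrix to CSV or JSON
#' @param W a [rate_matrix()].
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_rate_matrix <- function(W, path) {
  W <- as_rate_matrix(W)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(labels = rownames(W),
                              rates = unclass(W)),
                         path, auto_unbox = FALSE, digits = I(17))
  } else if (ext == "csv") {
    df <- data.frame(state = rownames(W),
                     apply(unclass(W), 2, function(col) sprintf("%.17g", col)),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    stop("unsupported rate-matrix format: .", ext)
  }
  invisible(path)
}

#' Write an entropy-rate time series with a metadata sidecar
#'
#' Writes the data frame as CSV at full double precision and a JSON
#' sidecar (`<path>.meta.json`) carrying the configuration, the seed and
#' the package version, so that a run is reproducible from its outputs
#' alone.
#'
#' @param df data frame (e.g. from [entropy_timeseries()]).
#' @param path CSV destination.
#' @param config named list echoed into the sidecar.
#' @param seed seed echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path, config = list(), seed = NULL) {
  stopifnot(is.data.frame(df))
  fmt <- df
  for (i in seq_along(fmt)) {
    if (is.numeric(fmt[[i]])) fmt[[i]] <- sprintf("%.17g", fmt[[i]])
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  meta <- list(config = config, seed = seed,
               package = "entroprod",
               version = as.character(utils::packageVersion("entroprod")),
               columns = names(df))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read back a time series written by [write_timeseries()]
#' @param path the CSV path.
#' @return list with `data` (data frame) and `meta` (sidecar list, or
#'   `NULL` when absent).
#' @export
read_timeseries <- function(path) {
  data <- utils::read.csv(path, check.names = FALSE)
  metafile <- paste0(path, ".meta.json")
  meta <- if (file.exists(metafile)) jsonlite::fromJSON(metafile) else NULL
  list(data = data, meta = meta)
}

run_config_fields <- c("system", "params", "times", "seed", "out", "tol")

#' Load and validate a run configuration
#'
#' JSON or YAML file describing a computation: which catalogue `system`,
#' its `params`, a `times` grid, and optional `seed`, `out`, `tol`.
#' Unknown keys are rejected (listing the valid ones) rather than
#' silently ignored; defaulted fields are recorded in the `defaulted`
#' attribute.
#'
#' @param path config file (`.json`, `.yaml`/`.yml`).
#' @return validated named list of class `"run_config"`.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the yaml package is required for YAML configs")
      }
      yaml::read_yaml(path)
    },
    stop("unsupported config format: .", ext))
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(run_config_fields, collapse = ", "))
  }
  if (is.null(cfg$system) || !is.character(cfg$system)) {
    stop("config needs a character 'system' field")
  }
  defaulted <- character(0)
  if (is.null(cfg$times)) { cfg$times <- seq(0.1, 5, by = 0.1); defaulted <- c(defaulted, "times") }
  if (!is.numeric(cfg$times) || any(cfg$times < 0)) {
    stop("'times' must be a non-negative numeric grid")
  }
  if (is.null(cfg$seed)) { cfg$seed <- 1L; defaulted <- c(defaulted, "seed") }
  if (is.null(cfg$tol)) { cfg$tol <- 1e-8; defaulted <- c(defaulted, "tol") }
  if (is.null(cfg$params)) cfg$params <- list()
  if (!is.null(cfg$params$rates)) {
    cfg$params$rates <- as.matrix(cfg$params$rates)
    if (any(cfg$params$rates[row(cfg$params$rates) != col(cfg$params$rates)] < 0)) {
      stop("config 'params$rates' has negative off-diagonal entries")
    }
  }
  structure(cfg, defaulted = defaulted, class = c("run_config", "list"))
}

#' Serialise a run configuration
#' @param cfg a [load_config()] result (or compatible list).
#' @param path destination (`.json` or `.yaml`).
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- cfg[intersect(run_config_fields, names(cfg))]
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs")
    }
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}
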