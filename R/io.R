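# Configuration files, trial-level CSV with an embedded provenance
# block, and JSON result export.

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration (by file extension) and
#' resolves it into model parameters plus run settings, filling in
#' the standard defaults for omitted keys. Recognized keys: `preset`
#' (`"14mo"`/`"24mo"`/`"36mo"`), the [model_params()] fields (`tau`,
#' `h`, `c_p`, `c_np`, `beta`, `noise_strength`, `dt`, `n_steps`,
#' `noise_dialect`), `n_participants`, `seed`,
#' `filter_perfect_training`, `strong`, `weak`. Giving both a
#' `preset` and an explicit dynamical constant is an error, as is any
#' unknown key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty
#'   file yields all defaults.
#' @return List with `params` (a `limbselect_params`), `scheme`,
#'   `n_participants`, `seed`, `filter`, and the raw `config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "yaml" = , "yml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)"))
  if (is.null(cfg)) cfg <- list()
  resolve_config(cfg)
}

# Validates a config list and fills defaults. Split out so the CLI
# can resolve flag-built lists through the same path.
resolve_config <- function(cfg) {
  stopifnot(is.list(cfg))
  par_keys <- c("tau", "h", "c_p", "c_np", "beta", "noise_strength",
                "dt", "n_steps", "noise_dialect")
  run_keys <- c("preset", "n_participants", "seed",
                "filter_perfect_training", "strong", "weak")
  unknown <- setdiff(names(cfg), c(par_keys, run_keys))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  dyn_keys <- setdiff(par_keys, c("dt", "n_steps", "noise_dialect"))
  if (!is.null(cfg$preset) && any(dyn_keys %in% names(cfg)))
    stop("config gives both a preset and explicit dynamical ",
         "constants (", paste(intersect(dyn_keys, names(cfg)),
                              collapse = ", "), "); use one or the other")
  params <- if (!is.null(cfg$preset)) {
    do.call(age_preset, c(list(name = cfg$preset),
                          cfg[intersect(c("dt", "n_steps",
                                          "noise_dialect"),
                                        names(cfg))]))
  } else {
    do.call(model_params, cfg[intersect(par_keys, names(cfg))])
  }
  scheme <- sensory_scheme(
    strong = if (is.null(cfg$strong)) 6.0 else cfg$strong,
    weak = if (is.null(cfg$weak)) 1.0 else cfg$weak)
  list(params = params, scheme = scheme,
       n_participants = if (is.null(cfg$n_participants)) 500L
                        else as.integer(cfg$n_participants),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       filter = isTRUE(cfg$filter_perfect_training),
       config = cfg)
}

# Full resolved configuration as a single-line JSON provenance block.
.provenance <- function(params, seed = NULL, extra = list()) {
  prov <- c(unclass(params),
            list(age_group = attr(params, "age_group"), seed = seed,
                 package = "limbselect",
                 version = as.character(utils::packageVersion("limbselect"))),
            extra)
  jsonlite::toJSON(prov[!vapply(prov, is.null, logical(1))],
                   auto_unbox = TRUE, digits = NA)
}

#' Write trial-level records to CSV
#'
#' Writes the `trials` data frame of a cohort or participant result
#' as plain CSV, preceded by `#`-prefixed header lines embedding the
#' full resolved configuration as JSON, so every artifact records how
#' it was produced.
#'
#' @param x A `limbselect_cohort`, `limbselect_participant`, or plain
#'   data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(x, path) {
  if (inherits(x, c("limbselect_cohort", "limbselect_participant"))) {
    prov <- .provenance(x$params, seed = x$seed)
    df <- x$trials
  } else {
    prov <- jsonlite::toJSON(list(package = "limbselect"),
                             auto_unbox = TRUE)
    df <- x
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", prov), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read trial-level records written by [write_trials_csv()]
#'
#' @param path CSV file path.
#' @return Data frame of trial records; the provenance JSON (if
#'   present) is attached as attribute `"provenance"`.
#' @export
read_trials_csv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (startsWith(first, "# provenance: "))
    attr(df, "provenance") <- jsonlite::fromJSON(
      sub("^# provenance: ", "", first))
  df
}
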