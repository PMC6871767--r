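# Configuration loading and deterministic table export: the plumbing layer
# shared by the command-line script in inst/cli.

#' Load a run configuration
#'
#' Reads a YAML or JSON configuration describing a model run. Exactly one
#' parameter source must be given: either `cancer` (a bundled cancer type)
#' or a `params` block with custom values (`delta`, `lambda`, `q` or
#' `alpha`/`beta`, `nu`, and optionally `M`, `N`). An optional `growth`
#' block (`kind`, `delta`, `K`, `gamma`, `resection: {time|size}`) overrides
#' the default exponential-resected growth; defaults follow the bundled
#' estimation chain (detection diameter 0.2 cm, dissemination size 1e8
#' cells, logistic carrying capacity 1e12 when `kind: logistic` gives no
#' `K`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `model` (a [relapse_model()]) and the raw
#'   `config`.
#' @export
load_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  has_cancer <- !is.null(cfg$cancer)
  has_params <- !is.null(cfg$params)
  if (has_cancer == has_params)
    stop("config must name exactly one parameter source: `cancer` or `params`",
         call. = FALSE)
  dissem <- cfg$dissemination_size %||% 1e8
  d_detect <- cfg$d_detect %||% 0.2
  params <- if (has_cancer) {
    inp <- clinical_inputs()
    row <- inp[inp$cancer_type == cfg$cancer, ]
    if (nrow(row) != 1)
      stop("config field `cancer`: unknown type '", cfg$cancer, "'",
           call. = FALSE)
    df <- estimate_parameters(row, d_detect = d_detect,
                              dissemination_size = dissem)
    model_params(delta = df$delta, lambda = df$lambda, alpha = df$alpha,
                 q = df$q, nu = df$nu, M = df$M, N = df$N)
  } else {
    pc <- cfg$params
    for (f in c("delta", "nu"))
      if (is.null(pc[[f]]))
        stop("config field `params.", f, "` is required", call. = FALSE)
    model_params(delta = pc$delta, lambda = pc$lambda, q = pc$q,
                 alpha = pc$alpha, beta = pc$beta, nu = pc$nu,
                 M = pc$M %||% size_from_diameter(d_detect), N = pc$N)
  }
  growth <- NULL
  if (!is.null(cfg$growth)) {
    gc <- cfg$growth
    kind <- gc$kind %||% "exponential"
    K <- gc$K %||% if (kind == "logistic") 1e12 else NULL
    growth <- growth_model(kind, delta = gc$delta %||% params$delta,
                           K = K, gamma = gc$gamma %||% 1)
    if (!is.null(gc$resection)) {
      growth <- set_resection(growth, time = gc$resection$time,
                              size = gc$resection$size)
    } else if (!is.null(params$N)) {
      growth <- set_resection(growth, size = params$N)
    }
  }
  model <- relapse_model(params, growth = growth)
  model$cancer_type <- if (has_cancer) cfg$cancer else NA_character_
  list(model = model, config = cfg)
}

#' Export a result table deterministically
#'
#' Writes a data frame as CSV (or JSON) with a fixed column order, a
#' provenance comment header, and no timestamps, so re-exports of the same
#' result are byte-identical.
#'
#' @param data A data frame.
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @param digits Significant digits used for numeric columns in CSV output
#'   (`NA` keeps full precision).
#' @return `path`, invisibly.
#' @export
export_table <- function(data, path, digits = NA) {
  stopifnot(is.data.frame(data))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(data, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  df <- as.data.frame(data)
  if (!is.na(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = digits)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# metarelapse ",
                    as.character(utils::packageVersion("metarelapse"))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [export_table()]
#'
#' @param path Path to a CSV written by [export_table()].
#' @return A tibble.
#' @export
read_exported_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
}
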