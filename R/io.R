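#' Named parameter presets
#'
#' Preset parameter blocks for the pathway and whole-cell models, by name:
#' `"metabolic-pathway"`, `"ribosomal-pathway"`, `"wholecell-default"`,
#' `"wholecell-theta46"` (metabolic reactions biased twice as strongly
#' towards transition-state limitation), and the pathway-length presets
#' `"N140"`, `"N150"`, `"N174"`, `"N206"`, `"N250"`, `"N259"`.
#'
#' @return named list of preset definitions (each a list of `model` and
#'   parameter fields).
#' @export
crowdcell_presets <- function() {
  npre <- lapply(metabolic_reaction_presets(), function(n)
    list(model = "wholecell", N = as.numeric(n)))
  names(npre) <- paste0("N", metabolic_reaction_presets())
  c(list(
    "metabolic-pathway" = list(model = "pathway", preset = "metabolic",
                               N = 20, kcat = 1, KM0 = 130, theta = 2.3),
    "ribosomal-pathway" = list(model = "pathway", preset = "ribosomal",
                               N = 20, kcat = 1, KM0 = 130, theta = 2.3),
    "wholecell-default" = list(model = "wholecell", N = 250, s_ext = 1,
                               theta_metabolic = 2.3, theta_ribosomal = 2.3),
    "wholecell-theta46" = list(model = "wholecell", N = 250, s_ext = 1,
                               theta_metabolic = 4.6, theta_ribosomal = 2.3)),
    npre)
}

rc_known_keys <- c("model", "preset", "N", "kcat", "KM0", "theta",
                   "theta_metabolic", "theta_ribosomal", "s_ext",
                   "r_s", "r_E", "topology", "objective",
                   "rho_min", "rho_max", "rho_step", "fine_min", "fine_max",
                   "rho_step_fine", "share_min", "share_max", "share_ratio",
                   "rho_grid", "n_restarts", "seed", "out", "format",
                   "rho_dm", "r", "mu", "law", "N_values", "s_ext_values")

#' Load and validate a run configuration
#'
#' Reads a JSON configuration (or takes fields directly as `...`), expands a
#' named preset, applies overrides (an explicit field wins over the preset
#' value), and validates the result: unknown keys are rejected by name and
#' `model` must be one of "pathway", "wholecell", "vazquez", "convert".
#'
#' @param path optional path to a JSON config file.
#' @param ... configuration fields overriding the file/preset.
#' @return an object of class `run_config` (validated named list).
#' @examples
#' load_run_config(preset = "ribosomal-pathway", seed = 7)
#' @export
load_run_config <- function(path = NULL, ...) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(cfg, list(...))
  if (!is.null(cfg$preset) && cfg$preset %in% names(crowdcell_presets())) {
    pre <- crowdcell_presets()[[cfg$preset]]
    keep <- setdiff(names(cfg), "preset")
    cfg <- utils::modifyList(pre, cfg[keep])  # explicit overrides win
  }
  unknown <- setdiff(names(cfg), rc_known_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model))
    stop("configuration must name a model (pathway/wholecell/vazquez/convert)")
  cfg$model <- match.arg(cfg$model,
                         c("pathway", "wholecell", "vazquez", "convert"))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

config_fingerprint <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

scan_as_table <- function(result) {
  if (inherits(result, "pathway_scan")) return(result$envelope)
  if (inherits(result, "wholecell_scan")) return(result$table)
  if (is.data.frame(result)) return(result)
  stop("unsupported result type: ", paste(class(result), collapse = "/"))
}

#' Write a scan result with provenance header
#'
#' Writes the tabular content of a scan (pathway envelope, whole-cell table,
#' or any data.frame) as CSV with `#`-prefixed provenance comment lines
#' (package version, timestamp-free config fingerprint, seed, full config
#' JSON) and floats at 12 significant digits, or as JSON. Two runs with
#' identical configuration and seed produce byte-identical files.
#'
#' @param result scan result or data.frame; must be non-empty.
#' @param path output file path.
#' @param format "csv" or "json".
#' @param config optional `run_config` recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scan <- function(result, path, format = c("csv", "json"),
                       config = NULL) {
  format <- match.arg(format)
  tab <- scan_as_table(result)
  if (is.null(tab) || nrow(tab) == 0) stop("empty result: nothing to write")
  header <- c(
    paste0("# crowdcell version=",
           as.character(utils::packageVersion("crowdcell"))),
    if (!is.null(config)) paste0("# config_md5=", config_fingerprint(config)),
    if (!is.null(config)) paste0("# seed=", config$seed),
    if (!is.null(config))
      paste0("# config=", jsonlite::toJSON(unclass(config),
                                           auto_unbox = TRUE, digits = NA)))
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  out[num] <- lapply(tab[num], function(x) signif(x, 12))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(out, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(list(provenance = header, data = out), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a scan CSV written by [write_scan()]
#'
#' @param path file path.
#' @return data.frame (provenance lines are skipped).
#' @export
read_scan <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
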