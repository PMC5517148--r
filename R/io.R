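# Result serialization, run manifests, scenario configuration files, and
# plain-text image readers for the command-line tools.

#' Write a simulation result as tidy CSV
#'
#' Columns: `iteration, terminal_id, origin_u, x, y, R_F, L_F, D` (one row
#' per recorded iteration and terminal; see
#' [as.data.frame.coadapt_sim()]). Written deterministically so identical
#' runs produce byte-identical files.
#'
#' @param result a `coadapt_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON manifest holding everything needed to reproduce the run
#' bit-identically: scenario builder and arguments, fully resolved
#' parameters (including the seed), package version and output paths.
#'
#' @param result a `coadapt_sim`.
#' @param scenario the scenario the result came from.
#' @param path output JSON file.
#' @param outputs named list/character of artifact paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(result, scenario, path, outputs = list()) {
  man <- list(tag = result$tag,
              scenario = scenario$call_info,
              params = unclass(result$params),
              package_version = as.character(utils::packageVersion("coadapt")),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              outputs = outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize and rebuild scenarios
#'
#' A scenario configuration records the builder name and its arguments, so
#' `build -> dump -> load -> build` round-trips to an identical scenario.
#'
#' @param scenario a `coadapt_scenario`.
#' @param path JSON file path.
#' @return For `write_scenario_config`, `path` invisibly; for
#'   `read_scenario_config`, the parsed config list; for
#'   `scenario_from_config`, the rebuilt `coadapt_scenario`.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' write_scenario_config(gap_assay_scenario(gap = 40), cfg)
#' sc2 <- scenario_from_config(read_scenario_config(cfg))
#' sc2$tag
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "coadapt_scenario"))
  jsonlite::write_json(scenario$call_info, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_config
#' @param path JSON file path.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$builder)) stop("config lacks a 'builder' field: ", path)
  cfg
}

#' @rdname write_scenario_config
#' @param config a parsed config list with `builder` and `args`.
#' @export
scenario_from_config <- function(config) {
  builders <- c("mapping_scenario", "gap_assay_scenario",
                "tectal_entry_scenario", "knockin_scenario",
                "innervation_scenario")
  if (!config$builder %in% builders)
    stop("unknown scenario builder '", config$builder, "'; valid: ",
         paste(builders, collapse = ", "))
  do.call(config$builder, as.list(config$args))
}

#' Named scenario presets
#'
#' One preset per simulated figure panel. `list_scenarios()` names them;
#' `preset_scenario(tag)` builds one. The presets are also shipped as JSON
#' configs under `system.file("extdata", "scenarios", package="coadapt")`.
#'
#' @return `list_scenarios()`: character vector of tags;
#'   `preset_scenario()`: a `coadapt_scenario`.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() names(scenario_presets())

scenario_presets <- function() {
  list(
    fig4b_coadapt = function() mapping_scenario(200, "coadaptation"),
    fig4b_canonical = function() mapping_scenario(200, "canonical"),
    fig4c_naive = function() gap_assay_scenario("ephrin", "ephrin", 20,
                                                naive = TRUE),
    fig4c_gap20 = function() gap_assay_scenario("ephrin", "ephrin", 20),
    fig4c_gap40 = function() gap_assay_scenario("ephrin", "ephrin", 40),
    fig4c_gap100 = function() gap_assay_scenario("ephrin", "ephrin", 100),
    fig4d_ephrin_eph = function() gap_assay_scenario("ephrin", "Eph", 20),
    fig4d_eph_ephrin = function() gap_assay_scenario("Eph", "ephrin", 20),
    fig10_entry_adapted = function() tectal_entry_scenario(200, 30),
    fig10_entry_naive = function() tectal_entry_scenario(200, 1),
    supp1a = function() innervation_scenario("single_fibers"),
    supp1b_het = function() knockin_scenario(2),
    supp1b_hom = function() knockin_scenario(4),
    supp1c = function() innervation_scenario("expansion"),
    supp1d = function() innervation_scenario("no_expansion_remnants"),
    supp1e = function() innervation_scenario("compression"),
    supp1f = function() innervation_scenario("mismatch"),
    supp1g = function() innervation_scenario("reversal"))
}

#' @rdname list_scenarios
#' @param tag preset name from [list_scenarios()].
#' @export
preset_scenario <- function(tag) {
  ps <- scenario_presets()
  if (!tag %in% names(ps))
    stop("unknown scenario '", tag, "'; valid: ",
         paste(names(ps), collapse = ", "))
  ps[[tag]]()
}

#' Read a grayscale image from a plain-text file
#'
#' Supports comma-separated numeric matrices (`.csv`) and ASCII portable
#' graymaps (`P2` `.pgm`). Intensities are rescaled to `[0, 1]`.
#'
#' @param path file path.
#' @return Numeric matrix (rows = y, columns = x).
#' @export
read_image_text <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (txt[1] != "P2") stop("only ASCII (P2) PGM images are supported")
    w <- as.integer(txt[2]); h <- as.integer(txt[3])
    maxv <- as.numeric(txt[4])
    v <- as.numeric(txt[-(1:4)])
    if (length(v) != w * h) stop("corrupt PGM: wrong pixel count")
    matrix(v / maxv, nrow = h, ncol = w, byrow = TRUE)
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    storage.mode(m) <- "double"
    if (any(!is.finite(m))) stop("image contains non-numeric entries")
    rng <- range(m)
    if (rng[2] > 1) m <- (m - rng[1]) / (rng[2] - rng[1])
    unname(m)
  }
}

#' @rdname read_image_text
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path (`.pgm` written as ASCII P2, otherwise CSV).
#' @param max_value gray levels for PGM output.
#' @export
write_image_text <- function(image, path, max_value = 255) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    v <- round(pmin(pmax(image, 0), 1) * max_value)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)),
                 as.character(max_value)), con)
    utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(image, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
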