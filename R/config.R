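#' Rubric configuration
#'
#' Every threshold and bin edge of the curation rubric in one validated list.
#' The defaults form the canonical profile `"salisbury-tsourkas-2019"`; any
#' value may be overridden, and output files record a hash of the active
#' configuration so deviations from the canonical profile are visible.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return An object of class `rubric_config`.
#' @section Defaults:
#' \describe{
#'   \item{min_orf_len}{76 (ORFs strictly longer than 75 bp)}
#'   \item{start_codons}{ATG, GTG, TTG}
#'   \item{coding_high / coding_sustain / coding_low}{0.75 / 0.5 / 0.25}
#'   \item{sim_sig / sim_mid / sim_strong}{1e-10 / 1e-20 / 1e-50}
#'   \item{overlap_bins}{10, 40, 70, 100 (left edges of the -1..-4 penalties)}
#'   \item{operon_overlaps}{1, 4, 8 bp exact stop/start overlaps}
#'   \item{divergent_gap}{50 bp promoter room for head-to-head pairs}
#'   \item{length_bins}{90, 120, 150, 200 (right edges of the -4..-1 penalties)}
#'   \item{keep_thresh / discard_thresh}{3 / 0}
#'   \item{large_overlap}{100 bp start-candidate disqualification}
#'   \item{sd_tie_tol}{0.1 (SD scores this close are tied)}
#'   \item{anchor_programs}{character(0): set to the two trusted callers whose
#'     joint calls define "strong" genes (classically Glimmer + GeneMark)}
#' }
#' @export
rubric_config <- function(...) {
  cfg <- list(
    profile = "salisbury-tsourkas-2019",
    min_orf_len = 76L,
    start_codons = c("ATG", "GTG", "TTG"),
    coding_high = 0.75,
    coding_sustain = 0.5,
    coding_low = 0.25,
    sim_sig = 1e-10,
    sim_mid = 1e-20,
    sim_strong = 1e-50,
    overlap_bins = c(10, 40, 70, 100),
    operon_overlaps = c(1L, 4L, 8L),
    divergent_gap = 50L,
    length_bins = c(90, 120, 150, 200),
    keep_thresh = 3L,
    discard_thresh = 0L,
    large_overlap = 100L,
    sd_tie_tol = 0.1,
    anchor_programs = character(0)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) || is.null(names(dots)) || any(!nzchar(names(dots)))) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
    if (length(dots)) cfg$profile <- "custom"
  }
  validate_config(cfg)
  structure(cfg, class = "rubric_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_orf_len >= 1,
    length(cfg$start_codons) >= 1, all(nchar(cfg$start_codons) == 3L),
    cfg$coding_high > cfg$coding_low,
    cfg$coding_sustain > 0, cfg$coding_sustain < 1,
    cfg$sim_strong < cfg$sim_mid, cfg$sim_mid < cfg$sim_sig,
    cfg$keep_thresh > cfg$discard_thresh,
    cfg$divergent_gap >= 0, cfg$large_overlap > 0, cfg$sd_tie_tol >= 0
  )
  if (length(cfg$overlap_bins) != 4L || is.unsorted(cfg$overlap_bins, strictly = TRUE)) {
    stop("'overlap_bins' must be 4 strictly increasing edges")
  }
  if (length(cfg$length_bins) != 4L || is.unsorted(cfg$length_bins, strictly = TRUE)) {
    stop("'length_bins' must be 4 strictly increasing edges")
  }
  invisible(cfg)
}

#' Write / read a rubric configuration as JSON
#'
#' @param config A [rubric_config()].
#' @param path File path.
#' @return `read_config` returns a [rubric_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rubric_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  profile <- raw$profile
  raw$profile <- NULL
  # empty JSON arrays simplify to list(); restore character vectors
  for (fld in c("start_codons", "anchor_programs")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as.character(unlist(raw[[fld]]))
    else if (fld %in% names(raw)) raw[[fld]] <- character(0)
  }
  cfg <- do.call(rubric_config, raw)
  if (!is.null(profile)) cfg$profile <- profile
  cfg$min_orf_len <- as.integer(cfg$min_orf_len)
  validate_config(cfg)
  cfg
}

#' Hash of a configuration (for provenance headers)
#' @param config A [rubric_config()].
#' @return Character md5 digest of the canonical JSON form.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
    tmp
  )
  unname(tools::md5sum(tmp))
}

#' Provenance header lines for output files
#' @param config A [rubric_config()].
#' @return Character vector of `#`-prefixed header lines.
#' @export
provenance_header <- function(config = rubric_config()) {
  c(
    sprintf("# phageCurate %s",
            as.character(utils::packageVersion("phageCurate"))),
    sprintf("# config_profile=%s config_hash=%s", config$profile,
            config_hash(config))
  )
}
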