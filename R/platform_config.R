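#' Construct and validate a culture-platform specification
#'
#' A `platform_spec` bundles the geometry and transport parameters of one of
#' the three organoid culture platforms: free drug in media (`"media"`), a
#' hydrogel slab under a media overlay (`"static_gel"`), or a perfused
#' multi-well bioreactor whose channel recirculates media from a reservoir
#' (`"bioreactor"`). Unspecified fields are filled from the packaged defaults
#' (see [platform_defaults()]).
#'
#' @param kind one of `"media"`, `"static_gel"`, `"bioreactor"`.
#' @param well_diameter well diameter in mm (standard 12-well plate: 22.1 mm).
#' @param gel_volume hydrogel volume in mL.
#' @param media_volume media volume in mL: the bath/overlay volume, or for the
#'   bioreactor the recirculating reservoir volume.
#' @param channel_diameter perfusion-channel diameter in mm (bioreactor only).
#' @param channel_axis_height height of the channel axis above the well floor
#'   in mm (bioreactor only); `NULL` means mid-height of the gel.
#' @param region_cut_distance lateral distance from the channel axis, in mm,
#'   at which the gel is partitioned into near/far regions (bioreactor only).
#' @param porosity hydrogel porosity (fluid volume fraction), in (0, 1].
#'   Stored for reference; the gel's solute transport is parameterized
#'   directly by the effective diffusivity `D_gel` and its solute capacity is
#'   the full bulk volume (see the methods vignette).
#' @param D_gel effective diffusivity of the drug in the gel, m^2/s. The
#'   packaged default is the value produced by
#'   [calibrate_effective_diffusivity()] (static gel reaching within 5% of
#'   equilibrium at 24 h) and is held fixed for all platforms.
#' @param D_media diffusivity of the drug in free media, m^2/s.
#' @param flow_rate perfusion flow rate in uL/min (bioreactor only).
#' @param applied_concentrations numeric vector of applied drug
#'   concentrations, uM.
#' @param duration total treatment duration in h.
#' @return an object of class `platform_spec`.
#' @examples
#' spec <- platform_spec("bioreactor")
#' spec$porosity          # 0.9
#' spec$channel_diameter  # 2.272 mm
#' @export
platform_spec <- function(kind = c("media", "static_gel", "bioreactor"),
                          well_diameter = NULL, gel_volume = NULL,
                          media_volume = NULL, channel_diameter = NULL,
                          channel_axis_height = NULL,
                          region_cut_distance = NULL, porosity = NULL,
                          D_gel = NULL, D_media = NULL, flow_rate = NULL,
                          applied_concentrations = NULL, duration = NULL) {
  kind <- match.arg(kind)
  defs <- platform_defaults()
  preset <- defs$platforms[[kind]]
  tr <- defs$transport
  spec <- list(
    kind = kind,
    well_diameter = well_diameter %||% preset$well_diameter,
    gel_volume = gel_volume %||% preset$gel_volume,
    media_volume = media_volume %||% preset$media_volume,
    channel_diameter = channel_diameter %||% preset$channel_diameter,
    channel_axis_height = channel_axis_height %||% preset$channel_axis_height,
    region_cut_distance = region_cut_distance %||% preset$region_cut_distance,
    porosity = porosity %||% tr$porosity,
    D_gel = D_gel %||% tr$D_gel,
    D_media = D_media %||% tr$D_media,
    flow_rate = flow_rate %||% preset$flow_rate,
    applied_concentrations = applied_concentrations %||%
      preset$applied_concentrations,
    duration = duration %||% preset$duration_h
  )
  class(spec) <- "platform_spec"
  validate_platform_spec(spec)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_platform_spec <- function(spec) {
  stopifnot(inherits(spec, "platform_spec"))
  chk_nonneg <- function(field) {
    v <- spec[[field]]
    if (!is.null(v) && (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)))
      stop("platform_spec: field '", field, "' must be finite and >= 0",
           call. = FALSE)
  }
  for (f in c("well_diameter", "gel_volume", "media_volume",
              "channel_diameter", "applied_concentrations", "duration",
              "D_gel", "D_media", "flow_rate"))
    chk_nonneg(f)
  if (!is.numeric(spec$porosity) || spec$porosity <= 0 || spec$porosity > 1)
    stop("platform_spec: field 'porosity' must lie in (0, 1]", call. = FALSE)
  req <- switch(spec$kind,
    media = c("applied_concentrations", "duration"),
    static_gel = c("well_diameter", "gel_volume", "media_volume",
                   "D_gel", "D_media", "duration"),
    bioreactor = c("well_diameter", "gel_volume", "media_volume",
                   "channel_diameter", "region_cut_distance", "flow_rate",
                   "D_gel", "duration"))
  for (f in req)
    if (is.null(spec[[f]]))
      stop("platform_spec: '", f, "' is required for kind '", spec$kind, "'",
           call. = FALSE)
  if (spec$kind == "bioreactor") {
    geo <- derive_geometry(spec)  # errors if the channel does not fit
    invisible(geo)
  }
  invisible(spec)
}

#' Load a platform specification from a YAML config
#'
#' The config document uses top-level keys `platform` (with a `kind` field and
#' any [platform_spec()] field to override), `transport`, `dosing`,
#' `simulation` and `seed`; all are optional except `platform.kind`.
#' Missing fields are filled from the packaged defaults, so
#' `load_platform_spec(list(platform = list(kind = "bioreactor")))` is the
#' default bioreactor.
#'
#' @param config path to a YAML file, or an already-parsed nested list.
#' @return a validated [platform_spec()].
#' @export
load_platform_spec <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a file path or a list")
  pl <- config$platform %||% list()
  if (is.null(pl$kind)) stop("config$platform$kind is required")
  tr <- config$transport %||% list()
  dosing <- config$dosing %||% list()
  platform_spec(
    kind = pl$kind,
    well_diameter = pl$well_diameter,
    gel_volume = pl$gel_volume,
    media_volume = pl$media_volume,
    channel_diameter = pl$channel_diameter,
    channel_axis_height = pl$channel_axis_height,
    region_cut_distance = pl$region_cut_distance,
    porosity = tr$porosity,
    D_gel = tr$D_gel,
    D_media = tr$D_media,
    flow_rate = pl$flow_rate,
    applied_concentrations = dosing$applied_concentrations,
    duration = dosing$duration_h
  )
}

#' Packaged platform presets and transport defaults
#'
#' Returns the packaged defaults shipped in
#' `inst/extdata/platform_defaults.yaml`: the three platform presets with
#' their applied-concentration panels (media 0--150 uM, static gel 0--300 uM,
#' bioreactor 0--600 uM), the transport parameters (effective gel diffusivity
#' from the 24-h static-gel calibration, free-media diffusivity, porosity)
#' and the default numerical settings.
#'
#' @return a nested list with elements `transport`, `simulation`, `platforms`.
#' @export
platform_defaults <- function() {
  path <- system.file("extdata", "platform_defaults.yaml",
                      package = "organodose", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Derive well/channel geometry from a platform spec
#'
#' Heights follow from volumes and the well cross-section; the perfusion
#' channel is taken to span the well along a diameter (channel length = well
#' diameter), at mid-gel height unless `channel_axis_height` says otherwise.
#'
#' @param spec a [platform_spec()].
#' @return an object of class `platform_geometry` with fields `well_area`
#'   (mm^2), `gel_height` (mm), `media_height` (mm, static gel),
#'   `channel_length` (mm), `channel_axis_height` (mm), `lumen_volume` (mL).
#' @examples
#' derive_geometry(platform_spec("static_gel"))$gel_height  # ~2.61 mm
#' @export
derive_geometry <- function(spec) {
  stopifnot(inherits(spec, "platform_spec"))
  area <- pi * (spec$well_diameter / 2)^2                    # mm^2
  gel_height <- if (!is.null(spec$gel_volume))
    spec$gel_volume * 1e3 / area else NULL                   # mm
  media_height <- if (spec$kind == "static_gel")
    spec$media_volume * 1e3 / area else NULL
  channel_length <- if (spec$kind == "bioreactor") spec$well_diameter else NULL
  axis_h <- NULL
  lumen_volume <- NULL
  if (spec$kind == "bioreactor") {
    axis_h <- spec$channel_axis_height %||% (gel_height / 2)
    r <- spec$channel_diameter / 2
    if (axis_h - r <= 0 || axis_h + r >= gel_height)
      stop("geometry error: channel (axis ", axis_h, " mm, radius ", r,
           " mm) does not fit inside the gel (height ",
           round(gel_height, 2), " mm)", call. = FALSE)
    lumen_volume <- pi * r^2 * channel_length * MM3_TO_ML
  }
  structure(list(well_area = area, gel_height = gel_height,
                 media_height = media_height,
                 channel_length = channel_length,
                 channel_axis_height = axis_h,
                 lumen_volume = lumen_volume),
            class = "platform_geometry")
}

#' @export
print.platform_spec <- function(x, ...) {
  cat("<platform_spec: ", x$kind, ">\n", sep = "")
  flds <- setdiff(names(x), "kind")
  for (f in flds) {
    v <- x[[f]]
    if (is.null(v)) next
    cat("  ", f, ": ", paste(signif(unlist(v), 6), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Serialize a platform spec to a YAML config document
#'
#' Inverse of [load_platform_spec()]: `load_spec(serialize) == spec`.
#'
#' @param spec a [platform_spec()].
#' @param path optional file to write; if `NULL` the YAML text is returned.
#' @export
serialize_platform_spec <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "platform_spec"))
  doc <- list(
    platform = Filter(Negate(is.null),
      spec[c("kind", "well_diameter", "gel_volume", "media_volume",
             "channel_diameter", "channel_axis_height",
             "region_cut_distance", "flow_rate")]),
    transport = spec[c("porosity", "D_gel", "D_media")],
    dosing = list(applied_concentrations = spec$applied_concentrations,
                  duration_h = spec$duration)
  )
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) { writeLines(txt, path); invisible(path) } else txt
}
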