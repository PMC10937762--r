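#' Construct a multi-channel imaging field
#'
#' A `ChannelStack` holds one imaging field: per-channel intensity arrays keyed
#' by biological role, plus acquisition metadata. Channels may be 2-D matrices
#' (`H x W`) or 3-D arrays (`H x W x Z`) for thin confocal stacks.
#'
#' @param channels named list of numeric matrices/arrays; names are channel
#'   roles among `nucleus_dye`, `neuron_marker`, `sting`, `effector`,
#'   `layer_marker`. `nucleus_dye` is mandatory: every quantification starts
#'   from the nuclear stain.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param z_step_um z-step between confocal planes in micrometres.
#' @param acquisition free-form metadata list.
#' @return An object of class `ChannelStack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 0.5, z_step_um = 1.6,
                          acquisition = list()) {
  stopifnot(is.list(channels), length(channels) >= 1L)
  roles <- names(channels)
  if (is.null(roles) || any(roles == ""))
    stop("all channels must be named by role")
  bad <- setdiff(roles, CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         "; known roles: ", paste(CHANNEL_ROLES, collapse = ", "))
  if (!"nucleus_dye" %in% roles)
    stop("configuration error: channel role 'nucleus_dye' is required")
  dims <- lapply(channels, function(x) dim(x)[1:2])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same H x W shape")
  if (any(vapply(channels, function(x) any(x < 0), logical(1))))
    stop("channel intensities must be non-negative")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, acquisition = acquisition),
            class = "ChannelStack")
}

#' @export
print.ChannelStack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<ChannelStack> %d channel(s) [%s], %d x %d px, %.3g um/px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], x$pixel_size_um))
  invisible(x)
}

n_z <- function(channel) if (length(dim(channel)) == 3L) dim(channel)[3] else 1L

#' Write a ChannelStack as a multi-page 16-bit TIFF with a YAML sidecar
#'
#' One TIFF page per channel plane (channel-major, z fastest); the sidecar
#' `<path>.yaml` records the page-to-role map, pixel size and z-step, so the
#' stack can be reloaded losslessly without external bookkeeping.
#'
#' @param stack a `ChannelStack`; intensities must lie in `[0, 65535]`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ChannelStack"))
  pages <- list()
  page_roles <- character(0)
  page_z <- integer(0)
  for (role in names(stack$channels)) {
    ch <- stack$channels[[role]]
    if (any(ch > 65535)) stop("intensities exceed 16-bit range in ", role)
    for (z in seq_len(n_z(ch))) {
      pl <- if (length(dim(ch)) == 3L) ch[, , z] else ch
      pages[[length(pages) + 1L]] <- round(pl) / 65535
      page_roles <- c(page_roles, role)
      page_z <- c(page_z, z)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pages = lapply(seq_along(page_roles), function(i)
    list(role = page_roles[i], z = page_z[i])),
    pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page TIFF into a ChannelStack
#'
#' The page-to-role map is taken from the YAML sidecar written by
#' [write_stack()], or from `channel_map` (a character vector of roles, one
#' per page, in page order). The load is lossless for 16-bit data.
#'
#' @param path TIFF file path.
#' @param channel_map optional character vector of roles, one per TIFF page;
#'   overrides the sidecar.
#' @param pixel_size_um,z_step_um metadata used when no sidecar is present.
#' @return A `ChannelStack`.
#' @export
read_stack <- function(path, channel_map = NULL, pixel_size_um = 0.5,
                       z_step_um = 1.6) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".yaml")
  if (is.null(channel_map) && file.exists(side)) {
    meta <- yaml::read_yaml(side)
    channel_map <- vapply(meta$pages, `[[`, character(1), "role")
    pixel_size_um <- meta$pixel_size_um
    z_step_um <- meta$z_step_um
  }
  if (is.null(channel_map))
    stop("configuration error: no YAML sidecar found and no channel_map given")
  if (length(channel_map) != length(pages))
    stop(sprintf("format error: file has %d page(s) but channel map names %d",
                 length(pages), length(channel_map)))
  channels <- list()
  for (role in unique(channel_map)) {
    planes <- lapply(pages[channel_map == role],
                     function(p) round(p * 65535))
    channels[[role]] <- if (length(planes) == 1L) planes[[1]] else
      array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  }
  channel_stack(channels, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                acquisition = list(source = path))
}

#' Project a z-stack to the 2-D working plane
#'
#' The acquisition protocol emulated here takes a handful of confocal planes
#' per field (1.6 um step); quantification operates on a per-channel 2-D
#' projection. Maximum projection is the default, the usual choice for sparse
#' punctate signal.
#'
#' @param stack a `ChannelStack`.
#' @param method one of `"max"`, `"mean"`, `"sum"`.
#' @return A `ChannelStack` whose channels are all 2-D; the method used is
#'   recorded under `acquisition$projection`.
#' @export
project_z <- function(stack, method = c("max", "mean", "sum")) {
  stopifnot(inherits(stack, "ChannelStack"))
  method <- match.arg(method)
  f <- switch(method, max = function(a) apply(a, c(1, 2), max),
              mean = function(a) apply(a, c(1, 2), mean),
              sum = function(a) apply(a, c(1, 2), sum))
  channels <- lapply(stack$channels, function(ch) {
    if (length(dim(ch)) == 3L) f(ch) else ch
  })
  acq <- stack$acquisition
  acq$projection <- method
  channel_stack(channels, pixel_size_um = stack$pixel_size_um,
                z_step_um = stack$z_step_um, acquisition = acq)
}
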