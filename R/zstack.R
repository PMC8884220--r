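#' Focal-plane z-stack container
#'
#' A `zstack` holds an ordered series of RGB focal-plane images of one lateral
#' field of view, acquired at successive axial (focus) positions. Plane 1 is
#' the shallowest; the axial coordinate of plane `i` is `(i - 1) * axial_step`
#' micrometres from the first plane.
#'
#' @param planes list of `H x W x 3` numeric arrays, all with identical
#'   dimensions; index 1 is the shallowest plane.
#' @param axial_step axial distance between consecutive planes, micrometres
#'   (strictly positive).
#' @param pixel_size lateral sampling, micrometres per pixel. The default
#'   0.065 corresponds to a large-format camera behind a 100x objective
#'   (~166 um field over 2560 px). Used only by the simulator, never by any
#'   fusion computation.
#' @param white_ref optional `H x W x 3` empty-field white reference image.
#' @param range declared pixel value range: `"unit"` for floats in \[0, 1\]
#'   or `"byte"` for integers in \[0, 255\]. Carried explicitly so that the
#'   mapping to the network's \[-1, 1\] input space is unambiguous.
#' @param meta free-form list of acquisition notes.
#'
#' @return An object of class `zstack`.
#' @export
zstack <- function(planes, axial_step, pixel_size = 0.065, white_ref = NULL,
                   range = c("unit", "byte"), meta = list()) {
  range <- match.arg(range)
  if (!is.list(planes) || length(planes) < 1L)
    stop("'planes' must be a non-empty list of H x W x 3 arrays")
  dims <- lapply(planes, dim)
  d1 <- dims[[1L]]
  if (length(d1) != 3L || d1[3L] != 3L)
    stop("each plane must be an H x W x 3 array")
  if (!all(vapply(dims, identical, logical(1), d1)))
    stop("all planes must share identical dimensions")
  if (!is.numeric(axial_step) || length(axial_step) != 1L || axial_step <= 0)
    stop("'axial_step' must be a single positive number (micrometres)")
  if (!is.null(white_ref) && !identical(dim(white_ref), d1))
    stop("'white_ref' must match the plane dimensions")
  structure(list(planes = planes, axial_step = axial_step,
                 pixel_size = pixel_size, white_ref = white_ref,
                 range = range, meta = meta),
            class = "zstack")
}

#' Number of focal planes in a stack
#' @param stack a [zstack].
#' @return integer plane count D.
#' @export
n_planes <- function(stack) length(stack$planes)

#' Axial extent spanned by a stack
#'
#' The distance between the first and the last focal plane,
#' `(D - 1) * axial_step` micrometres. A 14-plane stack at a 0.5 um step
#' spans 6.5 um.
#'
#' @param stack a [zstack].
#' @return axial extent in micrometres.
#' @export
axial_extent <- function(stack) (n_planes(stack) - 1L) * stack$axial_step

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes[[1L]])
  cat(sprintf("zstack: %d plane(s) of %d x %d px, axial step %g um (extent %g um), range [%s]\n",
              n_planes(x), d[1L], d[2L], x$axial_step, axial_extent(x),
              if (x$range == "unit") "0,1" else "0,255"))
  invisible(x)
}

range_max <- function(range) if (range == "byte") 255 else 1

#' Fused extended-depth-of-field image
#'
#' Container for a single fused RGB image together with its provenance:
#' which fusion method produced it and from how many source planes.
#'
#' @param image `H x W x 3` numeric array in \[0, 1\] (clipped on entry).
#' @param method one of `"wavelet"`, `"cami"`, `"plane_select"`.
#' @param source_planes number of focal planes that were fused.
#' @param source_step axial step of the source stack, micrometres.
#' @return An object of class `edof_image`.
#' @export
edof_image <- function(image, method = c("wavelet", "cami", "plane_select"),
                       source_planes, source_step) {
  method <- match.arg(method)
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("'image' must be an H x W x 3 array")
  structure(list(image = clip01(image), method = method,
                 source_planes = as.integer(source_planes),
                 source_step = source_step),
            class = "edof_image")
}

#' @export
print.edof_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("edof_image: %d x %d px, method '%s', fused from %d plane(s) at %g um\n",
              d[1L], d[2L], x$method, x$source_planes, x$source_step))
  invisible(x)
}

clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

#' Acquisition geometry of a brightfield objective
#'
#' @param wavelength emission wavelength, micrometres (e.g. 0.53 for green).
#' @param na numerical aperture of the objective (0 < NA <= 1.5).
#' @param sample_thickness axial thickness of the specimen slab, micrometres.
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(wavelength, na, sample_thickness) {
  stopifnot(wavelength > 0, na > 0, na <= 1.5, sample_thickness > 0)
  structure(list(wavelength = wavelength, na = na,
                 sample_thickness = sample_thickness),
            class = "acquisition_geometry")
}

#' Depth of field of an objective
#'
#' The axial range over which the sample appears acceptably sharp, using the
#' convention DoF = lambda / NA^2.
#'
#' @param geom an [acquisition_geometry].
#' @return depth of field in micrometres.
#' @export
depth_of_field <- function(geom) geom$wavelength / geom$na^2

#' Number of focal planes required to cover a specimen slab
#'
#' Np = ceil(St * NA^2 / (2 * lambda)): the number of axial samples needed to
#' cover a slab of thickness St at half the depth of field per step.
#'
#' @param geom an [acquisition_geometry].
#' @return integer plane count.
#' @export
required_planes <- function(geom) {
  as.integer(ceiling(geom$sample_thickness * geom$na^2 / (2 * geom$wavelength)))
}

#' Read a z-stack from a multi-page TIFF
#'
#' Pages are interpreted in file order as focal planes, page 1 = shallowest.
#' If a JSON sidecar written by [write_stack()] is present next to the file
#' (same path with extension `.json`), its metadata (axial step, pixel size,
#' value range) is used unless overridden by arguments.
#'
#' @param path path to a multi-page TIFF.
#' @param axial_step axial step in micrometres; required when no sidecar
#'   exists.
#' @param pixel_size lateral pixel size, micrometres per pixel.
#' @return a [zstack]. 8-bit files are read back as `"byte"` range with
#'   exact integer values; higher bit depths as `"unit"` floats.
#' @export
read_stack <- function(path, axial_step = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- sidecar_path(path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  if (is.null(axial_step)) axial_step <- meta$axial_step
  if (is.null(axial_step)) stop("'axial_step' not given and no sidecar metadata found")
  if (is.null(pixel_size)) pixel_size <- if (!is.null(meta$pixel_size)) meta$pixel_size else 0.065
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF contains no pages")
  dims <- lapply(pages, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1L]])))
    stop("TIFF pages have differing dimensions")
  bits <- attr(pages[[1L]], "bits.per.sample")
  byte <- !is.null(bits) && identical(as.integer(bits), 8L)
  planes <- lapply(pages, function(p) {
    p <- unclass(p)
    attributes(p) <- list(dim = dim(p))
    if (length(dim(p)) == 2L) p <- array(rep(p, 3L), c(dim(p), 3L))
    if (dim(p)[3L] > 3L) p <- p[, , 1:3, drop = FALSE]
    if (byte) round(p * 255) else p
  })
  zstack(planes, axial_step = axial_step, pixel_size = pixel_size,
         range = if (byte) "byte" else "unit",
         meta = list(source = path))
}

sidecar_path <- function(path) paste0(sub("\\.[Tt][Ii][Ff][Ff]?$", "", path), ".json")

#' Write a z-stack to a multi-page TIFF (plus JSON sidecar)
#'
#' Planes are written in axial order, one TIFF page per plane. `"byte"` range
#' stacks are written as 8-bit pages, round-tripping bit-exactly through
#' [read_stack()]; `"unit"` stacks are written as 16-bit. A JSON sidecar
#' carrying axial step, pixel size, value range and plane count is written
#' next to the TIFF.
#'
#' @param stack a [zstack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  if (length(stack$planes) == 0L) stop("refusing to write a stack with no planes")
  byte <- stack$range == "byte"
  pages <- lapply(stack$planes, function(p) if (byte) p / 255 else clip01(p))
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = if (byte) 8L else 16L),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("could not write TIFF to ", path)
  jsonlite::write_json(
    list(axial_step = stack$axial_step, pixel_size = stack$pixel_size,
         range = stack$range, n_planes = length(stack$planes)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' White-balance a focal plane against an empty-field reference
#'
#' Divides the plane, per channel, by the reference normalized to its
#' per-channel mean (flat-field correction). A spatially uniform reference is
#' therefore the identity; illumination gradients and colour casts present in
#' the reference are divided out. The result is clipped back to the declared
#' range.
#'
#' @param plane `H x W x 3` numeric array.
#' @param reference `H x W x 3` empty-field image, same shape.
#' @param range declared value range of both images, `"unit"` or `"byte"`.
#' @return white-balanced plane, same shape and range.
#' @export
white_balance <- function(plane, reference, range = c("unit", "byte")) {
  range <- match.arg(range)
  if (!identical(dim(plane), dim(reference)))
    stop("plane and reference must have identical dimensions")
  eps <- 1e-4 * range_max(range)
  if (any(reference < eps)) {
    warning("reference contains near-zero pixels; clamping to epsilon")
    reference[reference < eps] <- eps
  }
  out <- plane
  for (ch in 1:3) {
    ref_ch <- reference[, , ch]
    out[, , ch] <- plane[, , ch] / (ref_ch / mean(ref_ch))
  }
  hi <- range_max(range)
  out[out < 0] <- 0; out[out > hi] <- hi
  out
}

#' Apply white balancing to every plane of a stack
#'
#' Uses the stack's own `white_ref` unless a reference is supplied.
#'
#' @param stack a [zstack].
#' @param reference optional `H x W x 3` reference overriding `stack$white_ref`.
#' @return a white-balanced [zstack] (white_ref dropped).
#' @export
white_balance_stack <- function(stack, reference = NULL) {
  ref <- if (is.null(reference)) stack$white_ref else reference
  if (is.null(ref)) stop("no white reference available")
  planes <- lapply(stack$planes, white_balance, reference = ref, range = stack$range)
  zstack(planes, stack$axial_step, stack$pixel_size, white_ref = NULL,
         range = stack$range, meta = stack$meta)
}

#' Axially decimate a stack
#'
#' Emulates acquisition at a k-fold coarser axial step by retaining every
#' k-th plane starting from the k-th (indices k, 2k, 3k, ...). The output has
#' `floor(D / k)` planes at `k * axial_step` micrometres. This retention rule
#' is the one consistent with halving 14 planes to 7 (k = 2), reducing 14 to
#' 3 (k = 4), and 7 to 3 (k = 2).
#'
#' @param stack a [zstack] with D planes.
#' @param factor positive integer k, `1 <= k <= D`.
#' @return the decimated [zstack]; `factor = 1` returns the stack unchanged.
#' @export
decimate_stack <- function(stack, factor) {
  stopifnot(inherits(stack, "zstack"))
  k <- as.integer(factor)
  d <- n_planes(stack)
  if (is.na(k) || k < 1L) stop("'factor' must be a positive integer")
  if (k > d) stop("decimation factor ", k, " exceeds plane count ", d)
  if (k == 1L) return(stack)
  idx <- seq.int(k, d, by = k)
  zstack(stack$planes[idx], axial_step = k * stack$axial_step,
         pixel_size = stack$pixel_size, white_ref = stack$white_ref,
         range = stack$range, meta = stack$meta)
}

#' Map a stack to the network input range [-1, 1]
#'
#' Linearly maps the declared pixel range onto \[-1, 1\] (so 0 maps to -1 and
#' the range maximum to +1), matching the tanh output range of the fusion
#' network. The inverse mapping (offset and scale) is recorded in `meta$norm`
#' and undone by [denormalize_image()].
#'
#' @param stack a [zstack].
#' @return a [zstack] whose planes lie in \[-1, 1\]; `range` field is kept so
#'   the inverse map stays well-defined.
#' @export
normalize_for_network <- function(stack) {
  hi <- range_max(stack$range)
  planes <- lapply(stack$planes, function(p) 2 * (p / hi) - 1)
  meta <- stack$meta
  meta$norm <- list(scale = hi / 2, offset = hi / 2)  # x = scale*z + offset
  out <- stack
  out$planes <- planes
  out$meta <- meta
  out
}

#' Undo the [-1, 1] network mapping for one image
#'
#' @param img image in \[-1, 1\].
#' @param norm the `meta$norm` record from [normalize_for_network()], or NULL
#'   for the unit-range default.
#' @return image back on the original scale.
#' @export
denormalize_image <- function(img, norm = NULL) {
  if (is.null(norm)) norm <- list(scale = 0.5, offset = 0.5)
  norm$scale * img + norm$offset
}
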