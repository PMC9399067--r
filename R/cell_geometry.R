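# ---------------------------------------------------------------------------
# Cell geometry: floating (spherical) and attached (ellipsoidal) models,
# plus image-based cell sizing via a Hough circle transform.
# ---------------------------------------------------------------------------

#' Floating (spherical) cell geometry
#'
#' Concentric sphere model used for cells in suspension during the
#' radioactive incubation: nucleus of radius `nucleus_radius` centred in a
#' cell of radius `cell_radius`, with a thin bound-membrane shell of fixed
#' thickness 7.5 nm on the outside of the cell.
#'
#' @param cell_radius Cell radius R_C in micrometres.
#' @param nucleus_radius Nucleus radius R_N in micrometres (< R_C).
#' @param membrane_thickness Membrane shell thickness in micrometres
#'   (default 0.0075, i.e. 7.5 nm).
#' @return Object of class `floating_cell_geometry`.
#' @export
floating_cell_geometry <- function(cell_radius, nucleus_radius,
                                   membrane_thickness = 0.0075) {
  check_number(cell_radius, "cell_radius", lower = 0, allow_zero = FALSE)
  check_number(nucleus_radius, "nucleus_radius", lower = 0, allow_zero = FALSE)
  check_number(membrane_thickness, "membrane_thickness", lower = 0,
               allow_zero = FALSE)
  if (nucleus_radius >= cell_radius)
    stop_domain("nucleus_radius must be smaller than cell_radius")
  structure(list(cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius,
                 membrane_thickness = membrane_thickness),
            class = "floating_cell_geometry")
}

#' Attached (ellipsoidal) cell geometry
#'
#' Concentric, axis-aligned ellipsoid model for cells attached to the
#' culture plate during colony growth: nucleus semi-axes `(a, b, c)` inside
#' cytoplasm semi-axes `(a_cyt, b_cyt, c_cyt)`, with the `a/b` ratio shared
#' between nucleus and cytoplasm.
#'
#' @param a,b,c Nucleus semi-axes in micrometres (`c` is half the nucleus
#'   maximum thickness `h`).
#' @param a_cyt,b_cyt,c_cyt Cytoplasm (whole-cell) semi-axes in micrometres.
#' @param nucleus_offset Vertical displacement of the nucleus centre along
#'   the cell height (um); negative values sink the nucleus towards the
#'   basal membrane, as in adherent cells. Default 0 (concentric).
#' @return Object of class `attached_cell_geometry`.
#' @export
attached_cell_geometry <- function(a, b, c, a_cyt, b_cyt, c_cyt,
                                   nucleus_offset = 0) {
  for (v in list(a, b, c, a_cyt, b_cyt, c_cyt))
    check_number(v, "semi-axis", lower = 0, allow_zero = FALSE)
  check_number(nucleus_offset, "nucleus_offset")
  if (a_cyt <= a || b_cyt <= b || c_cyt < c)
    stop_domain("cytoplasm semi-axes must enclose the nucleus")
  if (abs(a / b - a_cyt / b_cyt) > 1e-6 * (a / b))
    stop_domain("a/b ratio must be preserved between nucleus and cytoplasm")
  # containment check of the displaced nucleus on a height grid
  z <- seq(nucleus_offset - c, nucleus_offset + c, length.out = 64)
  if (any(abs(z) >= c_cyt))
    stop_domain("displaced nucleus protrudes beyond the cell height")
  r_nuc <- a * sqrt(pmax(1 - ((z - nucleus_offset) / c)^2, 0))
  r_cyt <- a_cyt * sqrt(pmax(1 - (z / c_cyt)^2, 0))
  if (any(r_nuc > r_cyt + 1e-9))
    stop_domain("displaced nucleus protrudes through the cytoplasm")
  structure(list(a = a, b = b, c = c,
                 a_cyt = a_cyt, b_cyt = b_cyt, c_cyt = c_cyt,
                 nucleus_offset = nucleus_offset),
            class = "attached_cell_geometry")
}

#' Radius of the volume-equivalent sphere of an ellipsoid
#'
#' @param a,b,c Ellipsoid semi-axes (micrometres), all positive.
#' @return Radius of the sphere with volume `(4/3) pi a b c`, i.e.
#'   `(a b c)^(1/3)`.
#' @examples
#' equivalent_sphere_radius(8, 2, 4)  # 4
#' @export
equivalent_sphere_radius <- function(a, b, c) {
  if (any(c(a, b, c) <= 0) || any(!is.finite(c(a, b, c))))
    stop_domain("all semi-axes must be positive")
  (a * b * c)^(1 / 3)
}

#' Nucleus volume of a cell geometry
#' @param geometry A `floating_cell_geometry` or `attached_cell_geometry`.
#' @return Volume in cubic micrometres.
#' @export
nucleus_volume <- function(geometry) {
  if (inherits(geometry, "floating_cell_geometry"))
    return(4 / 3 * pi * geometry$nucleus_radius^3)
  if (inherits(geometry, "attached_cell_geometry"))
    return(4 / 3 * pi * geometry$a * geometry$b * geometry$c)
  stop_domain("unknown geometry class")
}

#' Cell (cytoplasm envelope) volume of a geometry
#' @param geometry A `floating_cell_geometry` or `attached_cell_geometry`.
#' @return Volume in cubic micrometres.
#' @export
cell_volume <- function(geometry) {
  if (inherits(geometry, "floating_cell_geometry"))
    return(4 / 3 * pi * geometry$cell_radius^3)
  if (inherits(geometry, "attached_cell_geometry"))
    return(4 / 3 * pi * geometry$a_cyt * geometry$b_cyt * geometry$c_cyt)
  stop_domain("unknown geometry class")
}

#' Volume of the bound-membrane shell of a floating cell
#' @param geometry A `floating_cell_geometry`.
#' @return Shell volume in cubic micrometres.
#' @export
membrane_shell_volume <- function(geometry) {
  stopifnot(inherits(geometry, "floating_cell_geometry"))
  r <- geometry$cell_radius
  t <- geometry$membrane_thickness
  4 / 3 * pi * ((r + t)^3 - r^3)
}

#' Build an attached-cell geometry from nucleus dimensions
#'
#' Constructs the ellipsoidal attached-cell model: the nucleus keeps the
#' semi-axes `(a, b, h/2)` measured on attached cells, the cytoplasm
#' semi-axes are scaled in-plane by `cytoplasm_scale` (preserving the a/b
#' ratio) and its height is then solved so that the cytoplasm volume equals
#' the spherical-equivalent floating cell volume.
#'
#' @param a,b Nucleus in-plane semi-axes (micrometres).
#' @param h Nucleus maximum thickness in micrometres; restricted to
#'   3, 4 or 5 (so `c = h/2`).
#' @param cytoplasm_scale In-plane scale factor applied to `a` and `b`
#'   (> 1; default 2.5).
#' @param floating_volume Target cytoplasm volume in cubic micrometres
#'   (the floating-cell volume `(4/3) pi R_C^3`).
#' @param basal_gap_um When non-`NULL`, the nucleus is sunk towards the
#'   basal membrane so that its lowest point sits this many micrometres
#'   above the cell bottom (adherent-cell morphology); `NULL` keeps the
#'   nucleus centred.
#' @return An `attached_cell_geometry` whose cell volume matches
#'   `floating_volume` exactly (well within the 1% requirement).
#' @export
build_attached_geometry <- function(a, b, h, cytoplasm_scale = 2.5,
                                    floating_volume, basal_gap_um = NULL) {
  check_number(a, "a", lower = 0, allow_zero = FALSE)
  check_number(b, "b", lower = 0, allow_zero = FALSE)
  if (!h %in% c(3, 4, 5))
    stop_domain("h must be one of 3, 4, 5 micrometres")
  check_number(cytoplasm_scale, "cytoplasm_scale", lower = 1,
               allow_zero = FALSE)
  if (cytoplasm_scale <= 1) stop_domain("cytoplasm_scale must exceed 1")
  cc <- h / 2
  v_nuc <- 4 / 3 * pi * a * b * cc
  check_number(floating_volume, "floating_volume", lower = 0,
               allow_zero = FALSE)
  if (floating_volume <= v_nuc)
    stop_domain("floating_volume must exceed the nucleus volume")
  a2 <- cytoplasm_scale * a
  b2 <- cytoplasm_scale * b
  c2 <- floating_volume / (4 / 3 * pi * a2 * b2)
  if (c2 < cc)
    stop_domain("volume constraint infeasible: cytoplasm thinner than ",
                "the nucleus; reduce cytoplasm_scale")
  off <- 0
  if (!is.null(basal_gap_um)) {
    check_number(basal_gap_um, "basal_gap_um", lower = 0)
    off <- -max(c2 - cc - basal_gap_um, 0)
  }
  attached_cell_geometry(a, b, cc, a2, b2, c2, nucleus_offset = off)
}

# ---------------------------------------------------------------------------
# Hough-transform circle detection for brightfield cell sizing
# ---------------------------------------------------------------------------

.sobel_gradient <- function(x) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(x, kx, boundary = "replicate")
  gy <- EBImage::filter2(x, t(kx), boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

.ring_kernel <- function(r, width = 0.9) {
  k <- 2L * ceiling(r) + 3L
  cen <- (k + 1) / 2
  d <- sqrt(outer((seq_len(k) - cen)^2, (seq_len(k) - cen)^2, `+`))
  ring <- abs(d - r) <= width
  m <- matrix(0, k, k)
  m[ring] <- 1 / sum(ring)
  m
}

#' Detect circular cells in a brightfield image (Hough transform)
#'
#' Circle detection by gradient-edge extraction followed by a radius-swept
#' circular Hough transform (ring-kernel convolution of the edge map).
#' Peaks are taken greedily by accumulator score with non-maximum
#' suppression at 1.2x the detected radius; the radius is refined by
#' parabolic interpolation across neighbouring radii. Detection is
#' invariant to affine rescaling of image intensities.
#'
#' @param image 2-D numeric matrix (grayscale).
#' @param radius_range_um Length-2 numeric: min and max circle radius to
#'   search, in micrometres.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param score_threshold Minimum fraction of the circle perimeter that
#'   must be covered by edge pixels (default 0.45).
#' @param max_detections Optional cap on the number of circles returned.
#' @return A list with `radii_um` (numeric vector), `detections`
#'   (`data.frame` with centres, radii and scores) and `summary`
#'   (min/mean/max/n). Empty with a warning when nothing is detected.
#' @export
detect_circle_radii <- function(image, radius_range_um, pixel_size_um,
                                score_threshold = 0.45,
                                max_detections = Inf) {
  stopifnot(is.matrix(image), length(radius_range_um) == 2L)
  if (any(!is.finite(image))) stop_domain("image must be finite-valued")
  check_number(pixel_size_um, "pixel_size_um", lower = 0, allow_zero = FALSE)
  if (any(radius_range_um <= 0) ||
      radius_range_um[2] < radius_range_um[1])
    stop_domain("radius_range_um must be positive and increasing")
  empty <- list(radii_um = numeric(),
                detections = data.frame(x = numeric(), y = numeric(),
                                        radius_px = numeric(),
                                        radius_um = numeric(),
                                        score = numeric()),
                summary = c(min = NA_real_, mean = NA_real_,
                            max = NA_real_, n = 0))
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: no circles detected")
    return(empty)
  }
  x <- (image - rng[1]) / diff(rng)
  gm <- .sobel_gradient(x)
  edges <- (gm >= 0.35 * max(gm)) * 1
  r_px <- seq(floor(radius_range_um[1] / pixel_size_um),
              ceiling(radius_range_um[2] / pixel_size_um), by = 1)
  r_px <- r_px[r_px >= 2]
  if (!length(r_px)) stop_domain("radius search range below 2 pixels")
  if (2 * max(r_px) > min(dim(image)))
    stop_domain("radius search range exceeds image extent")
  accs <- lapply(r_px, function(r)
    EBImage::filter2(edges, .ring_kernel(r), boundary = 0))
  best <- accs[[1L]]
  besti <- matrix(1L, nrow(best), ncol(best))
  if (length(accs) > 1L) {
    for (i in 2:length(accs)) {
      upd <- accs[[i]] > best
      best[upd] <- accs[[i]][upd]
      besti[upd] <- i
    }
  }
  det <- list()
  nr <- nrow(best); nc <- ncol(best)
  rowidx <- matrix(seq_len(nr), nr, nc)
  colidx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  while (length(det) < max_detections) {
    m <- max(best)
    if (!is.finite(m) || m < score_threshold) break
    at <- which.max(best)
    i <- ((at - 1L) %% nr) + 1L
    j <- ((at - 1L) %/% nr) + 1L
    ri <- besti[i, j]
    r0 <- r_px[ri]
    # parabolic refinement of the radius at this centre
    if (ri > 1L && ri < length(r_px)) {
      s0 <- accs[[ri - 1L]][i, j]; s1 <- accs[[ri]][i, j]
      s2 <- accs[[ri + 1L]][i, j]
      den <- s0 - 2 * s1 + s2
      if (is.finite(den) && den < 0)
        r0 <- r0 + 0.5 * (s0 - s2) / den
    }
    det[[length(det) + 1L]] <- c(x = i, y = j, radius_px = r0, score = m)
    supp <- (rowidx - i)^2 + (colidx - j)^2 <= (1.2 * r0)^2
    best[supp] <- -Inf
  }
  if (!length(det)) {
    warning("no circles detected")
    return(empty)
  }
  d <- as.data.frame(do.call(rbind, det))
  d$radius_um <- d$radius_px * pixel_size_um
  list(radii_um = d$radius_um,
       detections = d,
       summary = c(min = min(d$radius_um), mean = mean(d$radius_um),
                   max = max(d$radius_um), n = nrow(d)))
}
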