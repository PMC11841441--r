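#' Generate a synthetic bioprinted-grid image
#'
#' Binary image of a 3x3 grid test print: bright filament walls enclosing
#' nine pores of a prescribed shape, emulating the microscope image used to
#' score extrusion printability. Pore shapes: `"square"` (shape-fidelity
#' score Pr = 1), `"circle"` (Pr = pi/4) or `"star"` (a spiky polygon,
#' Pr > 1).
#'
#' `params`: `pore_shape` in `{"square","circle","star"}`, `pore_size` (um;
#' square side / circle diameter / star outer diameter), `wall` (filament
#' wall thickness, um). Optional: `star_points` (default 6), `star_inner`
#' (inner/outer radius ratio, default 0.45), `noise_sd`.
#'
#' @param spec a [synth_spec()] with `kind = "grid"`; `spec$shape` must be
#'   large enough to hold the 3x3 grid.
#' @return `list(stack, truth)`; `truth` carries each pore's true perimeter
#'   (px) and area (px^2) from the continuous generating geometry, and the
#'   implied Pr = p^2/(16 A) per pore.
#' @export
generate_grid_print <- function(spec) {
  stopifnot(spec$kind == "grid")
  shape <- match.arg(spec_param(spec, "pore_shape"), c("square", "circle", "star"))
  size_um <- spec_param(spec, "pore_size")
  wall_um <- spec_param(spec, "wall")
  noise_sd <- spec_param(spec, "noise_sd", 0)
  px <- spec$pixel_size
  s <- size_um / px       # pore size in px
  w <- wall_um / px
  if (s < 4) stopf("pore size %.1f um is below 4 px: perimeter estimation would be meaningless", size_um)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  pitch <- s + w
  grid_ext <- 3 * pitch + w
  if (grid_ext > min(nr, nc) - 4) {
    stopf("3x3 grid (%.0f px incl. walls) does not fit the %dx%d image", grid_ext, nr, nc)
  }
  or0 <- (nr - grid_ext) / 2  # grid origin offset (px, continuous coords)
  oc0 <- (nc - grid_ext) / 2

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- matrix(SYNTH_HIGH, nr, nc)        # material bright
  img[rows < or0 | rows > or0 + grid_ext |
      cols < oc0 | cols > oc0 + grid_ext] <- SYNTH_HIGH * 0.1  # outside the print

  star_poly <- function(cx, cy, r_out, r_in, npts) {
    ang <- seq(0, 2 * pi, length.out = 2 * npts + 1L)[-(2 * npts + 1L)] - pi / 2
    rad <- rep(c(r_out, r_in), npts)
    cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  }
  shoelace <- function(xy) {
    n <- nrow(xy); j <- c(2:n, 1L)
    abs(sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])) / 2
  }
  point_in_poly <- function(pr, pc, xy) {
    n <- nrow(xy); inside <- rep(FALSE, length(pr))
    j <- n
    for (i in seq_len(n)) {
      yi <- xy[i, 1L]; yj <- xy[j, 1L]; xi <- xy[i, 2L]; xj <- xy[j, 2L]
      cross <- ((yi > pr) != (yj > pr)) &
        (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
      j <- i
    }
    inside
  }

  pores <- list()
  for (gi in 0:2) for (gj in 0:2) {
    cr <- or0 + w + gi * pitch + s / 2
    cc <- oc0 + w + gj * pitch + s / 2
    if (shape == "square") {
      m <- abs(rows - cr) <= s / 2 & abs(cols - cc) <= s / 2
      p_true <- 4 * s; a_true <- s^2
    } else if (shape == "circle") {
      m <- (rows - cr)^2 + (cols - cc)^2 <= (s / 2)^2
      p_true <- pi * s; a_true <- pi * (s / 2)^2
    } else {
      npts <- spec_param(spec, "star_points", 6L)
      ratio <- spec_param(spec, "star_inner", 0.45)
      poly <- star_poly(cr, cc, s / 2, ratio * s / 2, npts)
      m <- matrix(point_in_poly(as.vector(rows), as.vector(cols), poly), nr, nc)
      p_true <- polyline_length(poly, closed = TRUE)
      a_true <- shoelace(poly)
    }
    img[m] <- SYNTH_HIGH * 0.1
    pores[[length(pores) + 1L]] <- list(
      center_px = c(cr, cc), perimeter_px = p_true, area_px2 = a_true,
      Pr = p_true^2 / (16 * a_true)
    )
  }

  img <- with_seed(spec$seed, {
    if (noise_sd > 0) img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc) else img
  })
  img <- quantize16(img)

  truth <- list(
    kind = "grid", pore_shape = shape,
    perimeter_px = vapply(pores, `[[`, numeric(1), "perimeter_px"),
    area_px2 = vapply(pores, `[[`, numeric(1), "area_px2"),
    Pr = vapply(pores, `[[`, numeric(1), "Pr"),
    pores = pores
  )
  list(stack = image_stack(img, pixel_size = px), truth = truth)
}
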