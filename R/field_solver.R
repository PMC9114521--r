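# 2D electrostatic field solver for electrode geometries.
#
# The stretching stress model needs the dimensionless geometric constant
# n = |E| r (d|E|/dx) / E0^2 at the cell position. Commercial FEM packages are
# usually used for this step; here a 5-point finite-difference Laplace solve on
# a uniform grid (Dirichlet electrode nodes, zero-normal-flux outer boundary)
# provides it in-repo. The channel height is uniform, so the electrode plane is
# treated in 2D.

#' Electrode geometry on a rectangular domain
#'
#' Defines the solver domain (in micrometres), the uniform grid spacing, and a
#' set of electrodes, each a polyline (or single point) at a fixed potential.
#' Grid nodes nearest the densified polylines become Dirichlet nodes; all outer
#' domain boundaries not covered by an electrode are insulating
#' (zero normal flux).
#'
#' @param width_um,height_um domain size, um.
#' @param spacing_um uniform grid spacing, um; must be > 0 and should be
#'   smaller than the narrowest electrode gap.
#' @param electrodes a list; each element is `list(points = <n x 2 matrix of
#'   (x, y) um coordinates>, potential = <V>)`.
#' @return an object of class `electrode_geometry`.
#' @examples
#' # parallel plates 10 um apart at 0 V and 1 V
#' geom <- electrode_geometry(10, 10, 0.5, list(
#'   list(points = cbind(0, c(0, 10)), potential = 0),
#'   list(points = cbind(10, c(0, 10)), potential = 1)))
#' @export
electrode_geometry <- function(width_um, height_um, spacing_um, electrodes) {
  if (!is.numeric(width_um) || width_um <= 0 ||
      !is.numeric(height_um) || height_um <= 0) {
    stop("domain dimensions must be positive (um)", call. = FALSE)
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0) {
    stop("`spacing_um` must be a single positive number", call. = FALSE)
  }
  if (!is.list(electrodes) || length(electrodes) < 2L) {
    stop("at least two electrodes are required", call. = FALSE)
  }
  pots <- vapply(electrodes, function(e) {
    if (is.null(e$points) || is.null(e$potential)) {
      stop("each electrode needs `points` and `potential`", call. = FALSE)
    }
    pts <- as.matrix(e$points)
    if (ncol(pts) != 2L || any(!is.finite(pts))) {
      stop("electrode `points` must be a finite n x 2 matrix", call. = FALSE)
    }
    if (any(pts[, 1] < 0 | pts[, 1] > width_um |
            pts[, 2] < 0 | pts[, 2] > height_um)) {
      stop("electrode points must lie inside the domain", call. = FALSE)
    }
    as.numeric(e$potential)
  }, numeric(1))
  if (length(unique(pots)) < 2L) {
    stop("electrodes must carry at least two distinct potentials",
         call. = FALSE)
  }
  structure(list(width_um = width_um, height_um = height_um,
                 spacing_um = spacing_um, electrodes = electrodes),
            class = "electrode_geometry")
}

#' Arc polyline helper
#'
#' Densely sampled circular-arc polyline, convenient for coaxial/wedge
#' electrode geometries.
#'
#' @param center length-2 numeric, arc centre (um).
#' @param radius arc radius (um).
#' @param theta_from,theta_to angular range in radians.
#' @param n number of samples.
#' @return an n x 2 coordinate matrix.
#' @export
arc_points <- function(center, radius, theta_from, theta_to, n = 400L) {
  th <- seq(theta_from, theta_to, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# internal: rasterize electrode polylines onto grid-node indices
rasterize_electrodes <- function(geom, nx, ny, h) {
  node_pot <- rep(NA_real_, nx * ny)
  for (e in geom$electrodes) {
    pts <- as.matrix(e$points)
    samples <- pts
    if (nrow(pts) > 1L) {
      segs <- lapply(seq_len(nrow(pts) - 1L), function(k) {
        p0 <- pts[k, ]; p1 <- pts[k + 1L, ]
        len <- sqrt(sum((p1 - p0)^2))
        m <- max(2L, ceiling(len / (h / 4)) + 1L)
        t <- seq(0, 1, length.out = m)
        cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
      })
      samples <- do.call(rbind, segs)
    }
    i <- pmin(pmax(round(samples[, 1] / h), 0L), nx - 1L) + 1L
    j <- pmin(pmax(round(samples[, 2] / h), 0L), ny - 1L) + 1L
    idx <- unique((j - 1L) * nx + i)
    clash <- !is.na(node_pot[idx]) & node_pot[idx] != e$potential
    if (any(clash)) {
      stop("electrodes at different potentials overlap on the grid; ",
           "refine the spacing or separate them", call. = FALSE)
    }
    node_pot[idx] <- e$potential
  }
  node_pot
}

# internal: central differences along matrix rows (x) with one-sided edges
grad_x <- function(M, h) {
  G <- M
  n <- nrow(M)
  if (n < 2L) return(G * 0)
  G[2:(n - 1), ] <- (M[3:n, ] - M[1:(n - 2), ]) / (2 * h)
  G[1, ] <- (M[2, ] - M[1, ]) / h
  G[n, ] <- (M[n, ] - M[n - 1, ]) / h
  G
}

#' Solve the 2D Laplace equation for an electrode geometry
#'
#' Five-point finite-difference discretization with Dirichlet conditions on
#' electrode nodes and second-order zero-normal-flux (mirror) conditions on the
#' outer boundary, assembled sparse and solved directly.
#'
#' The returned solution carries the potential grid (V), the field components
#' and magnitude (V/m), and the gradient of `|E|` (V/m^2), on grid coordinates
#' in um. The reference field `E0` defaults to the applied potential span
#' divided by the smallest gap between electrodes at different potentials.
#'
#' @param geom an [electrode_geometry()].
#' @param E0 optional reference field strength (V/m) overriding the default.
#' @return an object of class `field_solution`.
#' @export
solve_laplace_2d <- function(geom, E0 = NULL) {
  if (!inherits(geom, "electrode_geometry")) {
    stop("`geom` must be an electrode_geometry", call. = FALSE)
  }
  h <- geom$spacing_um
  nx <- round(geom$width_um / h) + 1L
  ny <- round(geom$height_um / h) + 1L
  if (nx < 3L || ny < 3L) stop("grid too coarse for the domain", call. = FALSE)

  node_pot <- rasterize_electrodes(geom, nx, ny, h)
  dirichlet <- !is.na(node_pot)
  if (!any(dirichlet)) stop("no electrode nodes on the grid", call. = FALSE)

  free <- which(!dirichlet)
  nfree <- length(free)
  if (nfree == 0L) stop("no free nodes: electrodes cover the whole grid",
                        call. = FALSE)
  free_rank <- rep(NA_integer_, nx * ny)
  free_rank[free] <- seq_len(nfree)

  ii <- ((free - 1L) %% nx) + 1L   # x index, 1..nx
  jj <- ((free - 1L) %/% nx) + 1L  # y index, 1..ny

  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  b <- numeric(nfree)
  add_dir <- function(di, dj) {
    # neighbour with mirror reflection at the outer boundary
    ni <- ii + di; nj <- jj + dj
    out <- ni < 1L | ni > nx | nj < 1L | nj > ny
    ni[out] <- ii[out] - di; nj[out] <- jj[out] - dj  # reflect inward
    nidx <- (nj - 1L) * nx + ni
    isdir <- dirichlet[nidx]
    # Dirichlet neighbours go to the RHS
    if (any(isdir)) {
      bb <- numeric(nfree)
      bb[isdir] <- node_pot[nidx[isdir]]
      b <<- b + bb
    }
    w <- which(!isdir)
    trip_i <<- c(trip_i, w)
    trip_j <<- c(trip_j, free_rank[nidx[w]])
    trip_x <<- c(trip_x, rep(-1, length(w)))
  }
  add_dir(1L, 0L); add_dir(-1L, 0L); add_dir(0L, 1L); add_dir(0L, -1L)
  trip_i <- c(trip_i, seq_len(nfree))
  trip_j <- c(trip_j, seq_len(nfree))
  trip_x <- c(trip_x, rep(4, nfree))

  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nfree, nfree))
  phi_free <- tryCatch(
    as.numeric(Matrix::solve(A, b)),
    error = function(e) stop("field solve failed: ", conditionMessage(e),
                             call. = FALSE))
  resid <- max(abs(as.numeric(A %*% phi_free) - b))
  scale <- max(abs(node_pot), na.rm = TRUE)
  if (scale > 0 && resid / scale > 1e-8) {
    stop(sprintf("field solve did not converge (relative residual %.3g)",
                 resid / scale), call. = FALSE)
  }

  phi <- matrix(NA_real_, nx, ny)
  phi[dirichlet] <- node_pot[dirichlet]
  phi[free] <- phi_free

  h_m <- h * 1e-6
  Ex <- -grad_x(phi, h_m)
  Ey <- -t(grad_x(t(phi), h_m))
  Emag <- sqrt(Ex^2 + Ey^2)
  dE_dx <- grad_x(Emag, h_m)
  dE_dy <- t(grad_x(t(Emag), h_m))

  pots <- node_pot[dirichlet]
  v_app <- max(pots) - min(pots)
  if (is.null(E0)) {
    gap_um <- min_electrode_gap(geom)
    if (geom$spacing_um >= gap_um) {
      warning("grid spacing is not smaller than the narrowest electrode gap")
    }
    E0 <- v_app / (gap_um * 1e-6)
  }

  structure(list(
    phi = phi, Ex = Ex, Ey = Ey, Emag = Emag,
    dE_dx = dE_dx, dE_dy = dE_dy,
    x_um = seq(0, by = h, length.out = nx),
    y_um = seq(0, by = h, length.out = ny),
    spacing_um = h, dirichlet = matrix(dirichlet, nx, ny),
    node_potential = matrix(node_pot, nx, ny),
    E0 = E0, applied_voltage = v_app, residual = resid
  ), class = "field_solution")
}

# internal: smallest distance between electrode point sets at distinct potentials
min_electrode_gap <- function(geom) {
  els <- geom$electrodes
  gap <- Inf
  for (a in seq_along(els)) {
    for (b in seq_along(els)) {
      if (b <= a) next
      if (els[[a]]$potential == els[[b]]$potential) next
      pa <- as.matrix(els[[a]]$points); pb <- as.matrix(els[[b]]$points)
      # chunked cross-distance; electrode polylines are small
      d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
      gap <- min(gap, sqrt(min(d2)))
    }
  }
  if (!is.finite(gap) || gap <= 0) {
    stop("could not determine a positive electrode gap", call. = FALSE)
  }
  gap
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d x %d grid, spacing %g um\n",
              length(x$x_um), length(x$y_um), x$spacing_um))
  cat(sprintf("  applied voltage %g V, E0 = %.4g V/m, residual %.2g\n",
              x$applied_voltage, x$E0, x$residual))
  invisible(x)
}

# internal: bilinear interpolation of a grid matrix at (x, y) in um
bilinear <- function(M, x_um, y_um, px, py) {
  h <- x_um[2] - x_um[1]
  fx <- (px - x_um[1]) / h
  fy <- (py - y_um[1]) / h
  i0 <- pmin(pmax(floor(fx), 0), length(x_um) - 2L)
  j0 <- pmin(pmax(floor(fy), 0), length(y_um) - 2L)
  tx <- fx - i0; ty <- fy - j0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  M[i0, j0] * (1 - tx) * (1 - ty) + M[i0 + 1L, j0] * tx * (1 - ty) +
    M[i0, j0 + 1L] * (1 - tx) * ty + M[i0 + 1L, j0 + 1L] * tx * ty
}

#' Field magnitude and gradient at a point
#'
#' Bilinear interpolation of `|E|` and of its central-difference gradient along
#' a stated axis at an interior point.
#'
#' @param solution a [solve_laplace_2d()] result.
#' @param point length-2 numeric, (x, y) in um; must lie inside the domain and
#'   off electrode nodes.
#' @param axis `"x"` (default; the stretching axis through the capture port)
#'   or `"y"`.
#' @return list with `E` (V/m) and `dE` (V/m^2, derivative of `|E|` along
#'   `axis`).
#' @export
field_at <- function(solution, point, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (!inherits(solution, "field_solution")) {
    stop("`solution` must be a field_solution", call. = FALSE)
  }
  px <- point[1]; py <- point[2]
  if (!is.numeric(point) || length(point) != 2L || any(!is.finite(point)) ||
      px < min(solution$x_um) || px > max(solution$x_um) ||
      py < min(solution$y_um) || py > max(solution$y_um)) {
    stop("`point` must lie inside the solver domain", call. = FALSE)
  }
  G <- if (axis == "x") solution$dE_dx else solution$dE_dy
  list(E = bilinear(solution$Emag, solution$x_um, solution$y_um, px, py),
       dE = bilinear(G, solution$x_um, solution$y_um, px, py))
}

#' Geometric constant of the stress model
#'
#' `n = |E(point)| * r * (d|E|/dx at point) / E0^2`, the dimensionless factor
#' converting the reference field strength into stretching stress at the cell.
#' It is invariant under rescaling of the applied voltage (both the numerator
#' and `E0^2` scale with V^2).
#'
#' @param solution a [solve_laplace_2d()] result.
#' @param cell_radius cell radius in m.
#' @param point evaluation point, (x, y) in um.
#' @param E0 reference field, V/m; defaults to the solution's reference.
#' @param axis gradient axis, `"x"` or `"y"`.
#' @return dimensionless `n` (signed: positive where `|E|` grows along the
#'   axis).
#' @export
geometric_constant <- function(solution, cell_radius, point,
                               E0 = solution$E0, axis = "x") {
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 == 0) {
    stop("`E0` must be a nonzero finite reference field (V/m)", call. = FALSE)
  }
  if (!is.numeric(cell_radius) || cell_radius <= 0) {
    stop("`cell_radius` must be positive (m)", call. = FALSE)
  }
  f <- field_at(solution, point, axis)
  f$E * cell_radius * f$dE / E0^2
}

#' Default capture-port demo geometry
#'
#' Two facing needle electrodes across a configurable gap (default 18 um, the
#' wide mouth of the capture port), mimicking the strongly nonuniform field at
#' a trap. Purely illustrative defaults; all dimensions configurable.
#'
#' @param gap_um electrode tip gap, um.
#' @param width_um,height_um domain size, um.
#' @param spacing_um grid spacing, um.
#' @param voltage applied potential difference, V (split symmetrically).
#' @return an [electrode_geometry()].
#' @export
capture_port_geometry <- function(gap_um = 18, width_um = 80, height_um = 40,
                                  spacing_um = 0.5, voltage = 10) {
  xl <- (width_um - gap_um) / 2
  xr <- (width_um + gap_um) / 2
  ym <- height_um / 2
  electrode_geometry(width_um, height_um, spacing_um, list(
    list(points = cbind(c(0, xl), c(ym, ym)), potential = +voltage / 2),
    list(points = cbind(c(xr, width_um), c(ym, ym)), potential = -voltage / 2)
  ))
}
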