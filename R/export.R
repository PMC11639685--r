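# Exchange formats: JSON NURBS (lossless, versioned schema), legacy VTK
# polydata tessellations, and binary little-endian STL.

ASSEMBLY_SCHEMA <- "thvforge-assembly/1"

curve_to_list <- function(cv) {
  list(type = "curve", degree = cv$degree,
       knots = cv$knots, control = cv$control, weights = cv$weights)
}

surface_to_list <- function(s) {
  list(type = "surface", degree_u = s$degree_u, degree_v = s$degree_v,
       knots_u = s$knots_u, knots_v = s$knots_v,
       n_u = dim(s$control)[1L], n_v = dim(s$control)[2L],
       control = matrix(s$control, ncol = 3L), weights = as.vector(s$weights))
}

list_to_curve <- function(l) {
  allowed <- c("type", "degree", "knots", "control", "weights")
  if (length(setdiff(names(l), allowed))) {
    stop("schema mismatch: unknown curve field(s): ",
         paste(setdiff(names(l), allowed), collapse = ", "), call. = FALSE)
  }
  nurbs_curve(do.call(rbind, lapply(l$control, unlist)),
              knots = unlist(l$knots),
              weights = unlist(l$weights), degree = l$degree)
}

list_to_surface <- function(l) {
  allowed <- c("type", "degree_u", "degree_v", "knots_u", "knots_v",
               "n_u", "n_v", "control", "weights")
  if (length(setdiff(names(l), allowed))) {
    stop("schema mismatch: unknown surface field(s): ",
         paste(setdiff(names(l), allowed), collapse = ", "), call. = FALSE)
  }
  ctrl <- array(do.call(rbind, lapply(l$control, unlist)),
                c(l$n_u, l$n_v, 3L))
  nurbs_surface(ctrl, knots_u = unlist(l$knots_u), knots_v = unlist(l$knots_v),
                weights = matrix(unlist(l$weights), l$n_u, l$n_v),
                degree_u = l$degree_u, degree_v = l$degree_v)
}

#' Export / import an assembly as JSON NURBS
#'
#' Versioned schema carrying every patch (degrees, knots, control points,
#' weights), the crossing-constraint map and the coupling-curve metadata.
#' Numbers are written with 17 significant digits, so geometry round-trips
#' bit-exactly.
#'
#' @param assembly A `valve_assembly`.
#' @param path Output file.
#' @return `path` invisibly (`export`), the reconstructed assembly
#'   (`import`).
#' @export
export_json_nurbs <- function(assembly, path) {
  obj <- list(
    schema = ASSEMBLY_SCHEMA,
    name = assembly$name,
    phi_max = assembly$phi_max,
    stent = list(
      curves = lapply(assembly$stent$curves, curve_to_list),
      section = assembly$stent$section,
      constraints = lapply(assembly$stent$constraints, function(g) {
        list(location = g$location, members = g$members,
             n_pairs = g$n_pairs, n_curves = g$n_curves,
             collinearity = g$collinearity)
      })),
    skirt = lapply(assembly$skirt, surface_to_list),
    leaflets = lapply(assembly$leaflets, surface_to_list),
    commissures = lapply(assembly$commissures, surface_to_list),
    coupling = list(
      shell_shell = lapply(assembly$coupling$shell_shell, function(set) {
        lapply(set, curve_to_list)
      }),
      shell_beam = lapply(assembly$coupling$shell_beam, curve_to_list)))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname export_json_nurbs
#' @export
import_json_nurbs <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  if (!identical(obj$schema, ASSEMBLY_SCHEMA)) {
    stop("schema mismatch: expected \"", ASSEMBLY_SCHEMA, "\", got \"",
         obj$schema, "\"", call. = FALSE)
  }
  structure(list(
    name = obj$name,
    stent = list(
      curves = lapply(obj$stent$curves, list_to_curve),
      section = unlist(obj$stent$section),
      constraints = structure(lapply(obj$stent$constraints, function(g) {
        list(location = unlist(g$location),
             members = do.call(rbind, lapply(g$members, unlist)),
             n_pairs = g$n_pairs, n_curves = g$n_curves,
             collinearity = g$collinearity)
      }), class = "constraint_map")),
    skirt = lapply(obj$skirt, list_to_surface),
    leaflets = lapply(obj$leaflets, list_to_surface),
    commissures = lapply(obj$commissures, list_to_surface),
    leaflet_curves = NULL,
    coupling = list(
      shell_shell = lapply(obj$coupling$shell_shell, function(set) {
        lapply(set, list_to_curve)
      }),
      shell_beam = lapply(obj$coupling$shell_beam, list_to_curve)),
    phi_max = obj$phi_max,
    components = NULL), class = "valve_assembly")
}

# --- tessellation -----------------------------------------------------------

# Chordal-tolerance grid tessellation of one surface patch; returns
# vertices (n x 3) and quad index matrix (m x 4, 1-based).
tessellate_surface <- function(srf, tol = 0.05, max_n = 257L) {
  dom <- surface_domain(srf)
  n <- 9L
  repeat {
    us <- seq(dom$u[1], dom$u[2], length.out = n)
    vs <- seq(dom$v[1], dom$v[2], length.out = n)
    # chordal deviation estimate at cell centers
    um <- (us[-1L] + us[-n]) / 2
    vm <- (vs[-1L] + vs[-n]) / 2
    dev <- 0
    corners <- eval_surface(srf, rep(us, times = n), rep(vs, each = n))
    cidx <- function(i, j) (j - 1L) * n + i
    mids <- eval_surface(srf, rep(um, times = n - 1L), rep(vm, each = n - 1L))
    for (j in seq_len(n - 1L)) {
      for (i in seq_len(n - 1L)) {
        avg <- (corners[cidx(i, j), ] + corners[cidx(i + 1L, j), ] +
                corners[cidx(i, j + 1L), ] + corners[cidx(i + 1L, j + 1L), ]) / 4
        dev <- max(dev, sqrt(sum((mids[(j - 1L) * (n - 1L) + i, ] - avg)^2)))
      }
    }
    if (dev <= tol || n >= max_n) break
    n <- 2L * n - 1L
  }
  quads <- matrix(0L, (n - 1L)^2, 4L)
  k <- 1L
  for (j in seq_len(n - 1L)) {
    for (i in seq_len(n - 1L)) {
      quads[k, ] <- c(cidx(i, j), cidx(i + 1L, j),
                      cidx(i + 1L, j + 1L), cidx(i, j + 1L))
      k <- k + 1L
    }
  }
  list(vertices = corners, quads = quads)
}

#' Export an assembly as legacy VTK polydata
#'
#' Surface patches are tessellated to the chordal tolerance and written as
#' quad polygons with per-patch component labels as cell data; stent curves
#' are written as polylines.
#'
#' @param assembly A `valve_assembly`.
#' @param path Output `.vtk` file.
#' @param tess_tol Chordal tolerance in mm (> 0).
#' @param curve_samples Samples per stent curve polyline.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(assembly, path, tess_tol = 0.05, curve_samples = 64L) {
  if (tess_tol <= 0) stop("tess_tol must be positive", call. = FALSE)
  verts <- list(); polys <- list(); lines <- list(); labels <- integer(0)
  offset <- 0L
  comp_id <- 0L
  for (f in c("skirt", "leaflets", "commissures")) {
    for (s in assembly[[f]]) {
      comp_id <- comp_id + 1L
      tess <- tessellate_surface(s, tess_tol)
      verts[[length(verts) + 1L]] <- tess$vertices
      polys[[length(polys) + 1L]] <- tess$quads + offset
      labels <- c(labels, rep(comp_id, nrow(tess$quads)))
      offset <- offset + nrow(tess$vertices)
    }
  }
  for (cv in assembly$stent$curves) {
    pts <- eval_curve(cv, seq(0, 1, length.out = curve_samples))
    verts[[length(verts) + 1L]] <- pts
    lines[[length(lines) + 1L]] <- seq_len(curve_samples) + offset
    offset <- offset + curve_samples
  }
  V <- do.call(rbind, verts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("thvforge assembly", assembly$name),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(V))), con)
  writeLines(apply(V, 1L, function(p) paste(format(p, digits = 12),
                                            collapse = " ")), con)
  np <- length(polys)
  nq <- sum(vapply(polys, nrow, integer(1L)))
  writeLines(sprintf("POLYGONS %d %d", nq, 5L * nq), con)
  for (P in polys) {
    writeLines(apply(P, 1L, function(q) paste(c(4L, q - 1L), collapse = " ")),
               con)
  }
  if (length(lines)) {
    tot <- sum(vapply(lines, length, integer(1L))) + length(lines)
    writeLines(sprintf("LINES %d %d", length(lines), tot), con)
    for (L in lines) {
      writeLines(paste(c(length(L), L - 1L), collapse = " "), con)
    }
  }
  writeLines(c(sprintf("CELL_DATA %d", nq + length(lines)),
               "SCALARS component int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(labels, rep(0L, length(lines)))), con)
  invisible(path)
}

#' Export an assembly's surfaces as binary STL
#'
#' Binary little-endian STL in mm; each quad of the chordal tessellation is
#' emitted as two triangles.
#'
#' @inheritParams export_vtk
#' @param path Output `.stl` file.
#' @return `path`, invisibly.
#' @export
export_stl <- function(assembly, path, tess_tol = 0.05) {
  if (tess_tol <= 0) stop("tess_tol must be positive", call. = FALSE)
  tris <- list()
  for (f in c("skirt", "leaflets", "commissures")) {
    for (s in assembly[[f]]) {
      tess <- tessellate_surface(s, tess_tol)
      V <- tess$vertices
      for (k in seq_len(nrow(tess$quads))) {
        q <- tess$quads[k, ]
        tris[[length(tris) + 1L]] <- V[q[c(1L, 2L, 3L)], ]
        tris[[length(tris) + 1L]] <- V[q[c(1L, 3L, 4L)], ]
      }
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "thvforge binary STL (mm)"))
  writeBin(header[1:80], con)
  writeBin(as.integer(length(tris)), con, size = 4L, endian = "little")
  for (tr in tris) {
    e1 <- tr[2L, ] - tr[1L, ]
    e2 <- tr[3L, ] - tr[1L, ]
    nrm <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
             e1[3L] * e2[1L] - e1[1L] * e2[3L],
             e1[1L] * e2[2L] - e1[2L] * e2[1L])
    nl <- sqrt(sum(nrm^2))
    if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, t(tr))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
  invisible(path)
}
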