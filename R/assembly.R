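# Full-valve assembly: the one-third soft goods replicated at 0/120/240
# degrees, the patterned stent with its crossing-constraint map, coupling
# curve metadata for downstream penalty coupling, and analysis refinement.

#' Assemble the full valve
#'
#' Builds the stent pattern and constraint map, the one-third skirt, one
#' leaflet and one commissural attachment, then replicates the soft goods by
#' rotation. Shell-shell coupling curves are the leaflet attachment and
#' vertical edges (leaflet-skirt and leaflet-commissure interfaces);
#' shell-beam penalty curves are the beam centerlines themselves.
#'
#' @param cfg A `valve_config`.
#' @param network_tol Network tolerance in mm.
#' @return Object of class `valve_assembly`.
#' @export
assemble_valve <- function(cfg, network_tol = 1e-6) {
  prof <- cfg$profile
  stent_curve <- build_stent_curve(prof, cfg$support)
  stent_curves <- pattern_curves(list(stent_curve, mirror_curve(stent_curve)),
                                 prof$phi_max)
  constraints <- crossing_constraints(stent_curves, profile = prof,
                                      phi_max = prof$phi_max)
  skirt <- build_skirt(cfg, network_tol)
  leaflet <- build_leaflet(cfg, network_tol)
  commissure <- leaflet$commissure
  if (is.null(skirt$surface) || is.null(leaflet$surface) ||
      is.null(commissure$surface)) {
    stop("assembly error: missing component", call. = FALSE)
  }
  rots <- c(0, 120, 240)
  structure(list(
    name = cfg$name,
    stent = list(curves = stent_curves,
                 section = cfg$materials$beam_section,
                 constraints = constraints),
    skirt = lapply(rots, function(a) rotate_z(skirt$surface, a)),
    leaflets = lapply(rots, function(a) rotate_z(leaflet$surface, a)),
    commissures = lapply(rots, function(a) rotate_z(commissure$surface, a)),
    leaflet_curves = lapply(rots, function(a) rotate_z(leaflet$curves, a)),
    coupling = list(
      shell_shell = lapply(rots, function(a) {
        list(leaflet_skirt = rotate_z(leaflet$curves$attachment, a),
             leaflet_commissure_left = rotate_z(leaflet$curves$left, a),
             leaflet_commissure_right = rotate_z(leaflet$curves$right, a))
      }),
      shell_beam = stent_curves),
    phi_max = prof$phi_max,
    components = list(skirt_third = skirt, leaflet = leaflet,
                      commissure = commissure)),
    class = "valve_assembly")
}

#' @export
print.valve_assembly <- function(x, ...) {
  cat(sprintf(paste0("<valve_assembly> %s: %d stent curves, %d skirt / %d ",
                     "leaflet / %d commissure patches, %d constraint groups\n"),
              x$name, length(x$stent$curves), length(x$skirt),
              length(x$leaflets), length(x$commissures),
              length(x$stent$constraints)))
  invisible(x)
}

#' Refine an assembly for analysis
#'
#' Uniform h-refinement per component; geometry is unchanged. Two stent
#' levels reproduce the published analysis discretizations (112 elements
#' per THV-A stent curve, 76 for THV-B).
#'
#' @param assembly A `valve_assembly`.
#' @param stent_levels,shell_levels Refinement levels (default 2 and 0).
#' @return The refined assembly.
#' @export
refine_for_analysis <- function(assembly, stent_levels = 2L,
                                shell_levels = 0L) {
  assembly$stent$curves <- lapply(assembly$stent$curves, h_refine_uniform,
                                  levels = stent_levels)
  for (f in c("skirt", "leaflets", "commissures")) {
    assembly[[f]] <- lapply(assembly[[f]], h_refine_uniform,
                            levels = shell_levels)
  }
  assembly
}

#' Per-component element counts
#'
#' @param assembly A `valve_assembly`.
#' @return List of element counts (spans) per component.
#' @export
element_report <- function(assembly) {
  list(
    stent = vapply(assembly$stent$curves, element_count, integer(1L) + 0),
    skirt = t(vapply(assembly$skirt,
                     function(s) element_count(s), numeric(3L))),
    leaflets = t(vapply(assembly$leaflets,
                        function(s) element_count(s), numeric(3L))),
    commissures = t(vapply(assembly$commissures,
                           function(s) element_count(s), numeric(3L))))
}

# All control points of an assembly (soft goods + stent), n x 3.
assembly_control_points <- function(assembly) {
  pts <- lapply(assembly$stent$curves, function(cv) cv$control)
  for (f in c("skirt", "leaflets", "commissures")) {
    pts <- c(pts, lapply(assembly[[f]],
                         function(s) matrix(s$control, ncol = 3L)))
  }
  do.call(rbind, pts)
}
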