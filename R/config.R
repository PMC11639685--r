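# Valve configuration layer: stent profile tables, support-point offset
# fractions, declarative curve recipes for the soft goods, and material
# parameters. Configurations are data (one YAML file per valve), so new
# valves are definable without code changes. Two fixtures ship with the
# package: THV-A (self-expanding, 11 profile points) and THV-B
# (balloon-expandable, 8 profile points).

CONFIG_SCHEMA <- "thvforge-valve/1"

config_file <- function(name) {
  p <- system.file("extdata", name, package = "thvforge")
  if (!nzchar(p)) p <- file.path("inst", "extdata", name)
  if (!file.exists(p)) stop("fixture file not found: ", name, call. = FALSE)
  p
}

#' Built-in valve configurations
#'
#' `thv_a()` is the tall self-expanding configuration (11 profile points,
#' 12 degree azimuthal half-period, 45 mm frame height); `thv_b()` the short
#' balloon-expandable one (8 points, 15 degrees, 20.05 mm, constant 13 mm
#' radius). Both carry the full material set (frame, leaflet, skirt,
#' penalties, beam cross-section).
#'
#' @return A `valve_config`.
#' @export
thv_a <- function() load_config(config_file("thv_a.yaml"))

#' @rdname thv_a
#' @export
thv_b <- function() load_config(config_file("thv_b.yaml"))

#' Load and validate a valve configuration file
#'
#' Performs strict schema validation (unknown keys rejected, profile
#' monotonicity, positive materials) and normalizes all units to mm and kPa
#' internally (frame modulus GPa -> kPa, shell thickness cm -> mm).
#'
#' @param path Path to a YAML valve description.
#' @return Object of class `valve_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed_top <- c("schema", "name", "profile", "support", "skirt",
                   "commissure", "leaflet", "materials")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown)) {
    stop("validation error: unknown top-level field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!identical(raw$schema, CONFIG_SCHEMA)) {
    stop("validation error: field 'schema' must be \"", CONFIG_SCHEMA, "\"",
         call. = FALSE)
  }
  for (f in allowed_top[-1L]) {
    if (is.null(raw[[f]])) {
      stop("validation error: missing field '", f, "'", call. = FALSE)
    }
  }
  pts <- do.call(rbind, lapply(raw$profile$points, function(p) {
    if (!setequal(names(p), c("r", "phi", "z"))) {
      stop("validation error: profile points need exactly fields r, phi, z",
           call. = FALSE)
    }
    data.frame(r = p$r, phi = p$phi, z = p$z)
  }))
  phi_max <- raw$profile$phi_max
  if (any(pts$r <= 0)) stop("profile error: r must be positive", call. = FALSE)
  if (any(diff(pts$z) <= 0)) {
    stop("profile error: z must be strictly increasing", call. = FALSE)
  }
  expect_phi <- rep_len(c(0, phi_max), nrow(pts))
  if (max(abs(pts$phi - expect_phi)) > 1e-9) {
    stop("profile error: phi must alternate between 0 and phi_max ",
         "starting at 0", call. = FALSE)
  }
  sup <- raw$support
  if (sup$end_fraction <= 0 || sup$end_fraction >= 0.5 ||
      sup$interior_fraction <= 0 || sup$interior_fraction >= 0.5) {
    stop("validation error: support fractions must lie in (0, 0.5)",
         call. = FALSE)
  }
  mat <- raw$materials
  ls_check <- function(m, label) {
    if (m$w < 0 || m$w > 1) {
      stop("validation error: ", label, " anisotropy weight w must be in [0,1]",
           call. = FALSE)
    }
    if (m$c0_kpa <= 0 || m$c1_kpa <= 0 || m$c2 <= 0) {
      stop("validation error: ", label, " Lee-Sacks parameters must be positive",
           call. = FALSE)
    }
  }
  ls_check(mat$leaflet, "leaflet")
  ls_check(mat$skirt, "skirt")
  materials <- list(
    frame = list(E = mat$frame$youngs_modulus_gpa * 1e6,     # kPa
                 nu = mat$frame$poisson,
                 rho = mat$frame$density_g_cm3),
    leaflet = list(c0 = mat$leaflet$c0_kpa, c1 = mat$leaflet$c1_kpa,
                   c2 = mat$leaflet$c2, c3 = mat$leaflet$c3,
                   w = mat$leaflet$w,
                   fiber_angle = mat$leaflet$fiber_angle_deg),
    skirt = list(c0 = mat$skirt$c0_kpa, c1 = mat$skirt$c1_kpa,
                 c2 = mat$skirt$c2, w = mat$skirt$w),
    shell = list(H = mat$shell$thickness_cm * 10,            # mm
                 rho = mat$shell$density_g_cm3),
    penalty = list(alpha_ss = mat$penalty$alpha_ss,
                   alpha_sb = mat$penalty$alpha_sb,
                   alpha_f = mat$penalty$alpha_f,
                   mu_friction = mat$penalty$mu_friction),
    beam_section = as.numeric(mat$beam_section_mm)           # mm (v2, v3)
  )
  cfg <- structure(list(
    name = raw$name,
    profile = list(points = pts, phi_max = phi_max),
    support = list(end_fraction = sup$end_fraction,
                   interior_fraction = sup$interior_fraction),
    skirt = raw$skirt,
    commissure = raw$commissure,
    leaflet = raw$leaflet,
    materials = materials,
    raw = raw), class = "valve_config")
  cfg
}

#' Serialize a valve configuration back to YAML
#'
#' Writes the loaded (unnormalized, original-unit) description so that
#' `load_config(serialize_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param cfg A `valve_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(cfg, path) {
  yaml::write_yaml(cfg$raw, path, precision = 15L)
  invisible(path)
}

#' @export
print.valve_config <- function(x, ...) {
  cat(sprintf("<valve_config> %s: %d profile points, phi_max %g deg, z in [%g, %g] mm\n",
              x$name, nrow(x$profile$points), x$profile$phi_max,
              min(x$profile$points$z), max(x$profile$points$z)))
  invisible(x)
}

# ---- point references and transforms ---------------------------------------

apply_transform_chain <- function(pt, transforms) {
  if (is.null(transforms)) return(pt)
  for (tr in transforms) {
    pt <- switch(tr$op,
      invert_phi = {
        cy <- cart_to_cyl(pt)
        drop(cyl_to_cart(cy[1L], -cy[2L], cy[3L]))
      },
      rotate_z = rotate_z(pt, tr$angle),
      reflect = reflect(pt, tr$plane),
      translate = translate(pt, as.numeric(tr$vector)),
      z_of = c(0, 0, pt[3L]),
      offset = {
        cy <- cart_to_cyl(pt)
        phi <- if (!is.null(tr$phi)) tr$phi else {
          if (cy[1L] < 1e-9) {
            stop("radial offset of an on-axis point needs an explicit phi",
                 call. = FALSE)
          }
          cy[2L]
        }
        radial <- if (is.null(tr$radial)) 0 else tr$radial
        vertical <- if (is.null(tr$vertical)) 0 else tr$vertical
        a <- deg2rad(phi)
        pt + c(radial * cos(a), radial * sin(a), vertical)
      },
      stop("unknown transform op: ", tr$op, call. = FALSE))
  }
  pt
}

#' Resolve a recipe point reference
#'
#' A reference names a baseline profile point (`"P3"`), one of its support
#' points (`support: above/below`), or a named context point provided by the
#' calling builder; the optional transform chain is applied left-to-right.
#'
#' @param ref List with fields `ref`, optional `support`, optional
#'   `transforms`.
#' @param profile The `profile` element of a `valve_config`.
#' @param support_cache Result of [support_points()] for the profile.
#' @param context Named list of builder-supplied points.
#' @return Length-3 Cartesian point (mm).
#' @export
resolve_point <- function(ref, profile, support_cache = NULL, context = list()) {
  nm <- ref$ref
  if (grepl("^P[0-9]+$", nm)) {
    idx <- as.integer(sub("^P", "", nm))
    if (idx < 1L || idx > nrow(profile$points)) {
      stop("resolution error: no baseline point ", nm, call. = FALSE)
    }
    if (!is.null(ref$support)) {
      if (is.null(support_cache)) {
        stop("resolution error: support reference without support cache",
             call. = FALSE)
      }
      side <- match.arg(ref$support, c("above", "below"))
      hit <- Filter(function(s) s$anchor_index == idx && s$side == side,
                    support_cache)
      if (!length(hit)) {
        stop("resolution error: point ", nm, " has no '", side,
             "' support", call. = FALSE)
      }
      pt <- hit[[1L]]$position
    } else {
      row <- profile$points[idx, ]
      pt <- drop(cyl_to_cart(row$r, row$phi, row$z))
    }
  } else {
    if (is.null(context[[nm]])) {
      stop("resolution error: unknown named point '", nm, "'", call. = FALSE)
    }
    pt <- as.numeric(context[[nm]])
  }
  apply_transform_chain(pt, ref$transforms)
}

# Resolve a whole recipe (list of refs) into an n x 3 matrix.
resolve_recipe <- function(recipe, profile, support_cache = NULL,
                           context = list()) {
  if (is.null(recipe) || !length(recipe)) {
    stop("recipe error: empty recipe", call. = FALSE)
  }
  t(vapply(recipe, resolve_point, numeric(3L), profile = profile,
           support_cache = support_cache, context = context))
}
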