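# Shared helpers: small curve constructors, exact nearest-neighbor set
# distance, and memoized valve fixtures (assemblies are deterministic, so
# one build per test run suffices).

straight_curve <- function(a, b, n = 4L) {
  a <- as.numeric(a); b <- as.numeric(b)
  f <- seq(0, 1, length.out = n)
  nurbs_curve(t(vapply(f, function(s) a + s * (b - a), numeric(3L))))
}

quarter_arc <- function(r = 1, z = 0) {
  circle_arc_3pt(c(r, 0, z), c(r / sqrt(2), r / sqrt(2), z), c(0, r, z))$curve
}

# max over rows of A of the distance to the nearest row of B
nn_max <- function(A, B) thvforge:::nn_max_distance(A, B)

.fix <- new.env()

fixture_config <- function(which = c("a", "b")) {
  which <- match.arg(which)
  key <- paste0("cfg_", which)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- if (which == "a") thv_a() else thv_b()
  }
  .fix[[key]]
}

fixture_assembly <- function(which = c("a", "b")) {
  which <- match.arg(which)
  key <- paste0("asm_", which)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- assemble_valve(fixture_config(which))
  }
  .fix[[key]]
}

fixture_leaflet <- function(which = c("a", "b")) {
  fixture_assembly(which)$components$leaflet
}
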