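# thvforge

Parametric, algorithmic NURBS modeling of stented transcatheter heart
valves (THVs) in R.

Transcatheter aortic valve replacement devices combine a wire stent frame,
a fabric/tissue skirt, three leaflets and three commissural attachments.
Designing and analyzing such devices computationally requires
*analysis-suitable* spline geometry: cubic NURBS centerline curves for the
frame wires (Bernoulli beams) and tensor-product NURBS surfaces for the
thin shells (Kirchhoff–Love), with explicit metadata about where wires
cross and where patches must be penalty-coupled. `thvforge` generates all
of this from a small declarative configuration, for engineers and
researchers building isogeometric structural or fluid–structure models of
THVs and for anyone exploring the device design space parametrically.

## The model

A valve is defined by a table of cylindrical coordinates
$(r_c, \phi_c, z_c)$ — one row per stent cross-section, azimuths
alternating between $0$ and $\phi_c^{\max}$ — plus support-point offset
fractions and curve recipes. From these the package constructs:

- **Stent**: a single clamped cubic B-spline whose control polygon
  interleaves the baseline points with support points (axial 12.5% offsets
  at interior crossings, 25% chord offsets at the apexes), mirrored across
  $\phi_c = 0$ and patterned in increments of $2\phi_c^{\max}$. Interior
  crossings carry three exactly collinear, exactly coincident control-point
  pairs, so the wires can be clamped together in analysis
  (`crossing_constraints()`).
- **Skirt**: a Gordon surface over rotated vertical profile curves and
  horizontal edge rings.
- **Commissures**: lofts of a central curve and its $\pm\phi_c^{\max}/6$
  rotated/reflected copies.
- **Leaflets**: Gordon surfaces over composite vertical edges (the
  commissure curve translated 0.12/0.15 mm toward the leaflet interior,
  joined to a lower section), a free edge, an attachment edge, a central
  belly curve and arc-length-offset interior curves.
- **Mechanical kernels**: beam section frames
  ($v_2 = v_1 \times \hat\phi_c$, $v_3 = v_1 \times v_2$), twist-free frame
  propagation, the Lee–Sacks energy
  $\psi_{el} = \frac{c_0}{2}(I_1-3) + \frac{c_1}{2}\bigl(w e^{c_2(I_1-3)^2}
  + (1-w) e^{c_3(I_4-1)^2} - 1\bigr)$ with analytic derivatives,
  shell–shell and shell–beam penalty parameters, and contact/friction
  kernels.

Two complete configurations ship with the package: `thv_a()` (tall
self-expanding frame, 45 mm, 11 profile points) and `thv_b()` (short
balloon-expandable frame, 20.05 mm, constant 13 mm radius, 8 points).

## Worked example

```r
library(thvforge)

cfg <- thv_a()
cfg
#> <valve_config> THV-A: 11 profile points, phi_max 12 deg, z in [0, 45] mm

stent <- build_stent_curve(cfg$profile)
stent
#> <nurbs_curve> degree 3, 31 control points, 28 spans, u in [0, 1]

element_count(h_refine_uniform(stent, 2))
#> [1] 112

asm <- assemble_valve(cfg)
asm
#> <valve_assembly> THV-A: 30 stent curves, 3 skirt / 3 leaflet / 3 commissure patches, 165 constraint groups

bounding_dims(asm)
#>       height max_diameter
#>         45.0         31.7

qc_report(asm)
#> <qc_report>
#>   radial symmetry   1.3e-14 mm
#>   mirror symmetry   8.61e-14 mm
#>   collinearity      0 mm
#>   network residual  7.67e-11 mm
#>   height            45.00 mm
#>   max diameter      31.70 mm
#>   orifice area      23.0 mm^2
#>   pass              TRUE
```

The 31 control points are the 11 table rows plus 20 support points; two
uniform h-refinement levels turn the 28 cubic spans into the 112 elements
used for beam analysis. The QC report confirms exact three-fold rotational
symmetry, mirror symmetry of the leaflet across $\phi_c = 60^\circ$,
collinear crossing triples, and sub-nanometre interpolation of every curve
network; height and diameter come straight from the profile table. The
orifice area is the projected opening enclosed by the three free edges in
top view (a geometric proxy, not a hemodynamic quantity).

Assemblies export losslessly to a versioned JSON NURBS schema and to
VTK/STL tessellations with a chordal tolerance:

```r
export_json_nurbs(asm, "thv_a.json")
export_vtk(asm, "thv_a.vtk", tess_tol = 0.05)
export_stl(asm, "thv_a.stl", tess_tol = 0.05)
```

A thin command-line front end lives at `inst/cli/thvforge.R`
(`generate`, `qc`, `validate` subcommands).

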