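---
title: "Parametric NURBS modeling of stented transcatheter heart valves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric NURBS modeling of stented transcatheter heart valves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thvforge)
```

## The modeling problem

A stented transcatheter heart valve (THV) consists of a wire frame (the
stent), a sealing membrane lining its lower interior (the skirt), three
tissue leaflets, and three commissural attachments joining the leaflets'
upper edges to the frame. `thvforge` constructs all of these as
analysis-suitable NURBS — cubic curves for the beam centerlines and
tensor-product surfaces for the thin shells — from a single declarative
configuration: a table of cylindrical coordinates $(r_c, \phi_c, z_c)$
describing the stent cross-sections, two support-point offset fractions,
and a set of curve recipes for the soft goods. Because every derived
structure is expressed in terms of the profile table, changing the table
(or the recipes) regenerates an entire device family; the two shipped
configurations, THV-A (tall, self-expanding, 11 profile points,
$\phi_c^{\max} = 12^\circ$) and THV-B (short, balloon-expandable, 8 points,
$\phi_c^{\max} = 15^\circ$), differ only in their data.

## Stent construction

The stent is one cubic B-spline curve, mirrored and rotationally patterned.
Its control polygon interleaves the *baseline* points of the profile table
with *support* points that enforce the correct tangent behavior at wire
crossings:

* interior connection points receive two supports offset **purely axially**
  (identical $r_c$, $\phi_c$) by 12.5% of the vertical gap to the adjacent
  cross-section below and above. The axial rule is a deliberate design
  choice: it makes the triple (support-below, baseline, support-above)
  exactly collinear, and it makes the supports of the mirrored-and-rotated
  partner wire land on *exactly* the same three locations, so each crossing
  can be treated as three shared control-point pairs that transfer moments
  between the wires. A chord-direction offset would break both properties.
* the bottom and top apex points receive one support on the chord toward
  their single neighbor, with the axial offset equal to 25% of the vertical
  gap. This yields the diamond-apex shape; exact $G^1$ continuity across an
  apex is impossible with a nonzero axial support offset, so the apex is
  position-continuous with mirror-symmetric tangents (kinked only
  azimuthally).

With $n$ baseline points this gives $3n - 2$ control points (31 for THV-A,
22 for THV-B), hence $3n - 5$ cubic spans (28 and 19), and after the two
uniform h-refinement levels used for analysis, 112 and 76 elements per
curve. The curve pair (original + mirror across $\phi_c = 0$) is rotated in
increments of $2\phi_c^{\max}$, producing 30 and 24 curves respectively.
`crossing_constraints()` recovers the coincident control-point groups by
rounding coordinates at $10^{-7}$ mm and merging location clusters whose
control-point indices are adjacent on both wires.

## Soft goods as curve networks

The skirt, commissures and leaflets are built for the third of the valve
between $\phi_c = 0^\circ$ and $120^\circ$ (mirror-symmetric across
$60^\circ$) and replicated by rotation.

**Skirt.** Two vertical profile curves (the stent $r(z)$ profile rotated
into a station plane) are patterned at every multiple of $\phi_c^{\max}$,
trimmed between a bottom and a top horizontal edge where necessary, and
combined with those edges into a bidirectional network. The fixture
horizontal edges are flat rings interpolated through rotations of the
lowest and highest skirt-profile points at *every* station, so each ring
passes exactly through the corresponding point of each vertical; the rings
sit at the inflow rim ($z = 0$) and at the skirt top ($z = 23.5$ mm for
THV-A, 20.05 mm for THV-B). A scalloped (zigzag) bottom edge is expressible
with the same recipe machinery, but the shipped fixtures use the flat rings:
a zigzag edge forces the skinning direction to interpolate an oscillating
control-point family, which produces multi-millimetre overshoot in the
control hull without changing the rendered membrane in a physically
meaningful way.

**Commissures.** A central curve at $\phi_c = 0$ is interpolated from
baseline/support references; the two edges are that curve rotated by
$\phi_c^{\max}/6$ about the axis ($2^\circ$ for THV-A, $2.5^\circ$ for
THV-B) and reflected across $\phi_c = 0$; the surface is the loft of
(edge$^-$, central, edge$^+$), so the mid-iso-curve is the central curve
itself.

**Leaflets.** The vertical edge is the commissure central curve translated
by 0.12 mm (THV-A) / 0.15 mm (THV-B) toward the leaflet interior, joined
($C^0$) to a lower section interpolated from transformed profile points,
then reflected across $60^\circ$. The translation direction is the unit
normal of the $\phi_c = 0$ plane ($+\hat y$): the central curve lies in that
plane, so its surface tangent normal to the plane is $\hat y$ to first
order. The free edge interpolates points sampled on the straight line from
the edge corner toward a near-axis point (at the height of the *bottom* of
the upper edge section when the free-edge center is lower than the corners,
of its *top* when the edge is flat), their mirror images, and a central
point offset radially and vertically from the axis in the $60^\circ$ plane.
Side fractions default to $(0.25, 0.5)$ — a choice, since only "specified
increments" are prescribed. The attachment edge and the central interior
(belly) curve follow the same recipe pattern; the interior horizontal curve
offsets the free-edge endpoints and center *by arc length* along their host
curves, by a configurable factor (default 1.0) of the upper-edge length,
and the free-edge side points by the same distance in $-z$. Arc length is
the only offset measure that is invariant under reparameterization of the
host curves, which is why it was chosen over parameter-space offsets.
THV-A adds one exact circular arc through the belly point and the two edge
points at its height.

## Gordon surfaces and the shared parameterization

A network surface is the classic Gordon combination
$G = L_1 + L_2 - T$: the loft of the u-curves at common v-stations, the
loft of the v-curves at common u-stations, and the tensor-product
interpolation of the intersection grid. The combination cancels exactly
along every network curve **only if** each curve meets the crossing family
at the *same* parameter values. Incoming curves rarely do, so each curve is
reparameterized: it is split at its own intersection parameters, each piece's
knot interval is mapped affinely onto the common station interval, and the
pieces are rejoined. This preserves the geometry *exactly* (splitting and
affine knot maps are exact operations); only the parameter speed becomes
piecewise-rescaled, which leaves $C^0$ parameter lines at interior stations
in the surface representation. Rational curves (the leaflet arc) cannot
enter the control-point-wise combination and are first replaced by
non-rational cubic interpolants, adaptively resampled to $10^{-9}$ mm.

Knot compatibility for lofting and for combining the three constituent
surfaces is always achieved by degree elevation plus knot-vector union —
never by re-approximation — so the interpolation property survives at
machine precision; the fixture networks close to $\sim 10^{-11}$ mm against
an $10^{-8}$ mm acceptance threshold. Degree elevation itself is an
internal utility (Bézier decomposition, exact in homogeneous coordinates);
stacking directions with fewer than four sections start below cubic and are
raised before combination.

## Numerical choices

* **Interpolation**: global interpolation with chord-length
  parameterization and averaged knots; the source text does not state its
  parameterization, and chord length is the standard shape-stable choice.
  End-derivative constraints are supported for cubic fits. Recipes with
  fewer than four points are fitted at degree $n-1$ and elevated to cubic.
* **Intersections**: $64\times64$ sampling grid seed, then damped Newton on
  the squared distance with analytic first and second curve derivatives;
  default network tolerance $10^{-6}$ mm.
* **Arc length**: per-span 16-point Gauss–Legendre with adaptive interval
  halving to $10^{-10}$ relative; arc-length inversion uses a 256-interval
  cumulative table refined by Newton steps with the exact speed.
* **Crossing grouping**: keys rounded at $10^{-7}$ mm, groups accepted
  within $10^{-6}$ mm; ties cannot arise on the fixtures because distinct
  control points are $\gtrsim 1$ mm apart.
* **Degenerate inputs**: zero vertical gaps in the profile, empty recipes,
  coincident interpolation points, antiparallel tangents in frame
  propagation, and non-divisible rotational increments all raise typed
  errors rather than producing geometry.
* **Units**: mm and kPa internally (frame modulus converted from GPa,
  shell thickness from cm); all public angles in degrees, radians internal.

## Mechanical kernels

The package evaluates, pointwise, the structural closures a downstream
isogeometric solver needs: the beam cross-section frame
($v_2 = v_1 \times \hat\phi_c$, $v_3 = v_1 \times v_2$, with the
$0.54 \times 0.21$ mm rectangular section along $v_2, v_3$), twist-free
frame propagation by successive minimal rotations between consecutive
tangents (Euler–Rodrigues; exact for planar curves at any station count),
the Lee–Sacks strain energy
$\psi = \tfrac{c_0}{2}(I_1 - 3) + \tfrac{c_1}{2}\left(w\,e^{c_2 (I_1-3)^2}
+ (1-w)\,e^{c_3 (I_4-1)^2} - 1\right)$
with analytic invariant derivatives, the shell–shell penalty pair (whose
ratio is $H^2/12$ by construction), the shell–beam penalty (minimum of the
shell and beam stiffness scales), the truncated linear contact kernel, and
the static-friction evaluator. The published listing writes the anisotropy
weight as $\delta$; it is stored as the energy's $w$ ($w = 0.9883$ for
leaflets) because the isotropic skirt model is printed with $\delta = 1$
and $w = 1$ is exactly the value that removes the $I_4$ term. Invariant
caps ($I_1 \le 12$, $I_4 \le 4$ by default) trigger warnings, never silent
clamping — the published stability constraint names the concept but no
values, so the caps are configurable.

## What the fixtures do and do not establish

The fixture geometries reproduce every published construction quantity
that is defined at desk scale: profile-table extents (heights 45.00 and
20.05 mm, THV-A max radius 15.85 mm, THV-B base diameter 26 mm),
control-point and element counts (31/22 points, 112/76 refined elements),
pattern counts (30/24 curves), commissure rotations, and the symmetry,
collinearity and interpolation invariants. The soft-good recipes beyond
what the construction text states explicitly (skirt edge selections,
leaflet lower-edge and attachment point lists, belly and free-edge offsets)
are approximations flagged `approximated_from_figure: true` in the YAML:
they produce geometrically consistent, mirror-symmetric valves of the
correct family, but are not claimed to duplicate the original figures
point-for-point. Nothing here simulates mechanics: crimping, deployment,
contact resolution and fluid–structure interaction are outside the scope
of this package, which is why the orifice-area metric is labeled a
geometric proxy (the projection of the free edges in top view) and is not
compared against hemodynamic opening areas.

One published quantity is knowingly *not* reproduced by the control-point
bounding box: a spline or rational representation of the THV-B $r = 13$ mm
skirt rings necessarily has control points outside the cylinder, so the
control-net diameter of the full THV-B assembly exceeds 26 mm by a few
percent. The sizing diameter is therefore exposed as `base_diameter()`
(twice the radius of the lowest baseline point), which is exact.

## Limitations

* Gordon surfaces carry $C^0$ parameter lines at interior network stations;
  downstream Kirchhoff–Love discretizations should re-refine or smooth if
  higher inter-element continuity is needed there (the analysis-refinement
  step is provided, uniformity is reported but not enforced).
* Degree elevation, trimmed surfaces and T-splines are out of scope; all
  public geometry is clamped cubic.
* The leaflet coaptation state is purely constructive — no contact-aware
  closing is performed.
* Problem sizes in the test suite (station counts, sample densities,
  refinement levels) match the fixture devices; they are the package's
  default working resolution, chosen so the whole geometric QC runs in
  seconds on a laptop core.
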