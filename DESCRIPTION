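Package: thvforge
Title: Parametric NURBS Modeling of Stented Transcatheter Heart Valves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Algorithmic, parameter-driven construction of transcatheter
    heart valve (THV) geometry as analysis-suitable NURBS. From a table of
    cylindrical stent profile coordinates the package generates the stent
    wireframe (baseline and support control points, mirrored and rotationally
    patterned cubic curves with crossing-constraint metadata), the skirt and
    leaflets as Gordon surfaces over bidirectional curve networks, and the
    commissural attachments as lofts. It ships two built-in valve
    configurations modeled on self-expanding and balloon-expandable devices,
    evaluable mechanical kernels (Bernoulli-beam cross-section frames,
    Lee-Sacks hyperelastic energy, penalty-coupling parameters, nonlocal
    contact and static-friction kernels), geometric quality-control metrics,
    and VTK/STL/JSON exporters for downstream isogeometric analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
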