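Package: actipath
Title: Adaptive Biasing Along Receptor Activation Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for mapping conformational free-energy landscapes along
    activation pathways with adaptive biasing. Implements ratchet-and-pawl
    adiabatic biased dynamics to generate transition pathways, agglomerative
    clustering and reference-state selection, path collective variables (the
    position s along and distance z from an ordered set of reference
    conformations), well-tempered metadynamics with hill bookkeeping and
    free-energy estimation, and reweighting of biased trajectories onto
    auxiliary order parameters such as the GPCR ionic-lock distance, the
    W6.48 toggle-switch dihedral, and the outward displacement of
    transmembrane helix 6. Ships seedable Langevin toy systems (analytic
    double wells and a labelled mini-receptor with inactive and active end
    states) so every component can be exercised and validated without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
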