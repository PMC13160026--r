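Package: spinedgg
Title: Graph-Grammar Simulation of Actin-Driven Dendritic Spine Head
    Morphodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulator of dendritic spine head morphodynamics in
    two dimensions. Actin filament networks are represented as labelled
    graphs rewritten by stochastic rules (a dynamical graph grammar) for
    polymerization, nucleotide dynamics, Arp2/3 branching, capping, cofilin
    binding, CaMKII-beta bundling, Aip1 severing and angle-gated breaking.
    Filament mechanics use a clipped Lennard-Jones separation potential and
    an angular bending energy with analytic gradients and Hessians driving
    overdamped gradient-descent kinetic rules and Metropolis-Hastings
    heat-bath thermal noise. The enclosing membrane is a polygon evolving
    under a discrete Helfrich curvature energy, coupled to filament ends by
    attachment objects and Brownian-ratchet gated polymerization. Includes
    well-mixed protein pools with synthesis/degradation dynamics, membrane
    morphometrics, parameter-sweep drivers, Pearson and Jonckheere-Terpstra
    trend statistics, and an epistasis change of variables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
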