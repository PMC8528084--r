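Package: toxpigis
Title: GIS-Ready ToxPi Glyph Layers and Local Hotspot Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes Toxicological Prioritization Index (ToxPi) slice and
    overall scores from a component data matrix, draws each record's ToxPi
    profile as geolocated wedge polygons in a projected equal-area
    coordinate system, assembles multi-scale feature layers (local glyphs,
    density-reduced glyphs, group-median glyphs, choropleths, maximum-radius
    rings), and runs Getis-Ord Gi* hotspot analysis with a seven-bin
    confidence classification.  All map products are emitted as standard
    GeoJSON (RFC 7946) with styling sidecars, so no proprietary GIS software
    is needed to create, share, or analyse the results.  Includes a
    synthetic county-lattice generator with a 4-domain / 14-slice pandemic
    vulnerability style model for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
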