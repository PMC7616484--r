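Package: imflow
Title: Modular Image and Object Analysis Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, modular workflow engine for automated analysis of
    multidimensional microscopy images. Named images and object sets flow
    through an ordered list of modules over a per-job workspace. Object
    voxel coordinates are stored interchangeably as pointlists, quadtrees
    or octrees behind a single access contract; objects carry measurements
    and hierarchical parent-child and partner relationships, supporting
    frame-to-frame tracking with linear-assignment linking, track motion
    statistics and skeleton edge/junction decomposition. Workflows are
    serialized as versioned JSON text, run in batch over folders of TIFF
    stacks, and results are exported to xlsx workbooks with the full
    workflow configuration embedded for provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    xml2,
    tiff,
    EBImage,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'imflow-package.R'
    'calibration.R'
    'coord-stores.R'
    'object-model.R'
    'image-stack.R'
    'workspace.R'
    'morphology.R'
    'workflow.R'
    'engine.R'
    'modules-image.R'
    'modules-objects.R'
    'tracking.R'
    'skeleton.R'
    'xlsx.R'
    'export.R'
    'batch.R'
    'fixtures.R'
    'builtin-modules.R'
    'zzz.R'
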