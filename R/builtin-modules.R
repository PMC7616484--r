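# Built-in workflow modules. Each body receives (params, ws, seed) and
# wires the corresponding package function into the workspace; output
# names equal to input names update the stored item in place.

.putImageResult <- function(ws, img, inputName) {
  if (identical(img$name, inputName)) putItem(ws, img, "update")
  else putItem(ws, img, "create")
}

.registerBuiltinModules <- function() {
  registerModule("load_image", function(params, ws, seed) {
    path <- params$path
    if (is.null(path) || !nzchar(path)) path <- ws$metadata$sourcePath
    putItem(ws, loadImage(path, name = params$output_image), "create")
  }, "Read a TIFF stack from file into the workspace")

  registerModule("apply_threshold", function(params, ws, seed) {
    img <- getItem(ws, params$input_image, "image")
    res <- applyThreshold(
      img,
      algorithm = if (is.null(params$algorithm)) "otsu" else params$algorithm,
      manualValue = params$manual_value,
      scope = if (is.null(params$scope)) "global" else params$scope,
      outputName = params$output_image)
    .putImageResult(ws, res, params$input_image)
  }, "Binarise an image by an automatic (Otsu) or manual threshold")

  registerModule("fill_holes", function(params, ws, seed) {
    img <- getItem(ws, params$input_image, "image")
    out <- params$output_image
    res <- fillHoles(img, outputName = if (is.null(out)) params$input_image
                     else out)
    .putImageResult(ws, res, params$input_image)
  }, "Fill enclosed background regions, per slice and timepoint")

  registerModule("identify_objects", function(params, ws, seed) {
    img <- getItem(ws, params$input_image, "image")
    set <- identifyObjects(
      img, params$output_objects,
      inPlane = if (is.null(params$connectivity)) 4L
      else as.integer(params$connectivity),
      volumetric = if (is.null(params$volumetric)) 6L
      else as.integer(params$volumetric),
      storeMethod = if (is.null(params$store_method)) "pointlist"
      else params$store_method)
    putItem(ws, set, "create")
  }, "Connected-components labelling of a binary image into objects")

  registerModule("measure_object_shape", function(params, ws, seed) {
    measureObjectShape(getItem(ws, params$input_objects, "objects"))
  }, "Add voxel-count, area/volume, centroid and bounding-box measurements")

  registerModule("filter_objects", function(params, ws, seed) {
    filterObjects(getItem(ws, params$input_objects, "objects"),
                  measurement = params$measurement,
                  predicate = params$predicate,
                  threshold = as.numeric(params$threshold),
                  mode = if (is.null(params$mode)) "remove" else params$mode)
  }, "Remove or keep objects by comparing a measurement to a threshold")

  registerModule("track_objects", function(params, ws, seed) {
    set <- getItem(ws, params$input_objects, "objects")
    tracks <- trackObjects(
      set, maxDist = as.numeric(params$max_linking_distance),
      trackName = params$output_objects,
      altFactor = if (is.null(params$alternative_factor)) 1.05
      else as.numeric(params$alternative_factor))
    putItem(ws, tracks, "create")
  }, "Frame-to-frame linear-assignment tracking into Track parents")

  registerModule("measure_track_motion", function(params, ws, seed) {
    measureTrackMotion(getItem(ws, params$input_objects, "objects"),
                       childClass = params$child_class)
  }, "Path length, displacement, directionality, velocity per track")

  registerModule("skeleton_decompose", function(params, ws, seed) {
    img <- getItem(ws, params$input_image, "image")
    res <- skeletonDecompose(img, edgeName = params$output_edge_objects,
                             junctionName = params$output_junction_objects)
    putItem(ws, res$edges, "create")
    putItem(ws, res$junctions, "create")
  }, "Thin to a skeleton and split into partnered Edge/Junction objects")

  registerModule("prune_terminal_edges", function(params, ws, seed) {
    pruneTerminalEdges(getItem(ws, params$input_objects, "objects"),
                       getItem(ws, params$junction_objects, "objects"))
  }, "Remove skeleton edges connected to exactly one junction")

  registerModule("add_outline_overlay", function(params, ws, seed) {
    img <- getItem(ws, params$input_image, "image")
    objs <- getItem(ws, params$input_objects, "objects")
    res <- addOutlineOverlay(img, objs, seed = seed,
                             outputName = params$output_image)
    .putImageResult(ws, res, params$input_image)
  }, "Colour object outlines over the image (seeded colours)")

  registerModule("save_image", function(params, ws, seed) {
    img <- getItem(ws, params$input_image, "image")
    path <- params$path
    if (dir.exists(path) || grepl("/$", path)) {
      base <- ws$metadata$filename
      base <- if (nzchar(base)) tools::file_path_sans_ext(base)
      else sprintf("job%03d", ws$metadata$jobIndex)
      path <- file.path(sub("/$", "", path),
                        paste0(base, "_", img$name, ".tif"))
    }
    saveImage(img, path)
  }, "Write an image to a TIFF file (with calibration sidecar)")

  registerModule("remove_image", function(params, ws, seed) {
    removeItem(ws, params$input_image, "image")
  }, "Drop an image from the workspace to free memory")

  registerModule("remove_objects", function(params, ws, seed) {
    removeItem(ws, params$input_objects, "objects")
  }, "Drop an object set from the workspace (links are severed)")

  registerModule("workflow_condition", function(params, ws, seed) {
    cond <- list(target = params$target, name = params$item,
                 measurement = params$measurement,
                 operator = params$operator,
                 threshold = as.numeric(params$threshold),
                 action = params$action, label = params$label)
    evaluateCondition(cond, ws)
  }, "Terminate or skip forward when a count/measurement predicate holds")

  invisible(NULL)
}
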