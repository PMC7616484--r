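# The canonical nucleus-segmentation pipeline: load -> threshold (in a new
# image) -> fill holes in place -> identify -> measure -> size-filter ->
# outline overlay -> save. Mirrors the classic six-stage workflow used in
# the end-to-end tests.
nucleusWorkflow <- function(minArea = 10, outDir = tempdir(),
                            removeBinary = FALSE) {
  mods <- list(
    moduleSpec("load_image",
               wfParam("path", "file-path", "", visible = TRUE),
               wfParam("output_image", "output-image", "Raw"),
               nickname = "Load image"),
    moduleSpec("apply_threshold",
               wfParam("input_image", "input-image", "Raw"),
               wfParam("output_image", "output-image", "Binary"),
               wfParam("algorithm", "choice", "otsu",
                       choices = c("otsu", "manual")),
               nickname = "Apply threshold"),
    moduleSpec("fill_holes",
               wfParam("input_image", "input-image", "Binary"),
               wfParam("output_image", "output-image", "Binary"),
               nickname = "Fill holes"),
    moduleSpec("identify_objects",
               wfParam("input_image", "input-image", "Binary"),
               wfParam("output_objects", "output-objects", "Nuclei"),
               wfParam("connectivity", "number", 4),
               wfParam("store_method", "choice", "quadtree",
                       choices = c("pointlist", "quadtree", "octree")),
               nickname = "Identify objects"),
    moduleSpec("measure_object_shape",
               wfParam("input_objects", "input-objects", "Nuclei"),
               nickname = "Measure object shape"),
    moduleSpec("filter_objects",
               wfParam("input_objects", "input-objects", "Nuclei"),
               wfParam("measurement", "text", "AREA_PX"),
               wfParam("predicate", "choice", "<",
                       choices = c("<", "<=", ">", ">=")),
               wfParam("threshold", "number", minArea, visible = TRUE),
               wfParam("mode", "choice", "remove",
                       choices = c("remove", "keep")),
               nickname = "Filter objects"),
    moduleSpec("add_outline_overlay",
               wfParam("input_image", "input-image", "Raw"),
               wfParam("input_objects", "input-objects", "Nuclei"),
               wfParam("output_image", "output-image", "Annotated"),
               nickname = "Add overlay"),
    moduleSpec("save_image",
               wfParam("input_image", "input-image", "Annotated"),
               wfParam("path", "file-path", paste0(outDir, "/")),
               nickname = "Save image"))
  if (removeBinary)
    mods <- append(mods, list(
      moduleSpec("remove_image",
                 wfParam("input_image", "input-image", "Binary"),
                 nickname = "Remove images")), after = 6)
  do.call(workflow, mods)
}

# write a blob fixture to a TIFF and return its path
writeBlobTiff <- function(dir, name, nBlobs = 5, seed = 1,
                          radiusRange = c(4, 12)) {
  fix <- makeBlobImage(nBlobs = nBlobs, seed = seed,
                       radiusRange = radiusRange)
  path <- file.path(dir, name)
  saveImage(fix$image, path)
  path
}
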