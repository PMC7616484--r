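#' Per-job workspace
#'
#' A workspace is the common data store of one analysis job: it maps
#' user-defined names to images and object sets, and carries job metadata
#' (source path, filename, folder, series name, job index). In batch mode
#' each job gets its own workspace; workspaces never interact. Contents are
#' discarded after export — persistence happens only through save/export
#' modules.
#'
#' @field images environment mapping name to \code{\link{ImageStack}}.
#' @field objectsets environment mapping name to \code{\link{ObjectSet}}.
#' @field metadata list: sourcePath, filename, folder, seriesName, jobIndex.
#' @export Workspace
#' @exportClass Workspace
Workspace <- setRefClass("Workspace",
  fields = list(
    images = "environment",
    objectsets = "environment",
    metadata = "list"
  ),
  methods = list(
    initialize = function(...) {
      initFields(images = new.env(parent = emptyenv()),
                 objectsets = new.env(parent = emptyenv()),
                 metadata = list(sourcePath = "", filename = "", folder = "",
                                 seriesName = "", jobIndex = 1L))
      callSuper(...)
      images <<- new.env(parent = emptyenv())
      objectsets <<- new.env(parent = emptyenv())
      invisible(.self)
    },
    imageNames = function() sort(ls(images)),
    objectSetNames = function() sort(ls(objectsets)),
    show = function() {
      cat(sprintf("<Workspace job %d: images [%s], object sets [%s]>\n",
                  metadata$jobIndex,
                  paste(imageNames(), collapse = ", "),
                  paste(objectSetNames(), collapse = ", ")))
    }
  )
)

#' Create a workspace
#'
#' @param sourcePath path of the input file driving this job ("" for
#'   jobs not driven by a file).
#' @param seriesName series identifier (empty for single-series formats).
#' @param jobIndex 1-based index of the job within a batch.
#' @return A \code{Workspace} reference object.
#' @export
newWorkspace <- function(sourcePath = "", seriesName = "", jobIndex = 1L) {
  ws <- Workspace$new()
  ws$metadata <- list(
    sourcePath = sourcePath,
    filename = if (nzchar(sourcePath)) basename(sourcePath) else "",
    folder = if (nzchar(sourcePath)) dirname(sourcePath) else "",
    seriesName = seriesName,
    jobIndex = as.integer(jobIndex)
  )
  ws
}

#' Store an image or object set in a workspace
#'
#' \code{mode = "create"} requires the name to be unused in its namespace;
#' \code{mode = "update"} requires it to exist already and replaces the
#' pixel / coordinate content while keeping the named entity (downstream
#' references and image measurements survive). Images and object sets live
#' in separate namespaces.
#'
#' @param ws a \code{\link{Workspace}}.
#' @param item an \code{\link{ImageStack}} or \code{\link{ObjectSet}}.
#' @param mode "create" or "update".
#' @return \code{ws}, invisibly.
#' @export
putItem <- function(ws, item, mode = c("create", "update")) {
  mode <- match.arg(mode)
  if (is(item, "ImageStack")) {
    nm <- item$name
    env <- ws$images
    exists_ <- exists(nm, envir = env, inherits = FALSE)
    if (mode == "create" && exists_)
      stop(sprintf("image '%s' already exists in the workspace", nm))
    if (mode == "update") {
      if (!exists_)
        stop(sprintf("cannot update image '%s': not in the workspace", nm))
      old <- get(nm, envir = env, inherits = FALSE)
      old$setData(item$data)
      old$calibration <- item$calibration
      return(invisible(ws))
    }
    assign(nm, item, envir = env)
  } else if (is(item, "ObjectSet")) {
    nm <- item$className
    env <- ws$objectsets
    exists_ <- exists(nm, envir = env, inherits = FALSE)
    if (mode == "create" && exists_)
      stop(sprintf("object set '%s' already exists in the workspace", nm))
    if (mode == "update" && !exists_)
      stop(sprintf("cannot update object set '%s': not in the workspace", nm))
    assign(nm, item, envir = env)
  } else {
    stop("item must be an ImageStack or an ObjectSet")
  }
  invisible(ws)
}

#' Retrieve an image or object set by name
#'
#' @param ws a \code{\link{Workspace}}.
#' @param name stored name.
#' @param kind "image" or "objects".
#' @return The stored \code{ImageStack} or \code{ObjectSet}.
#' @export
getItem <- function(ws, name, kind = c("image", "objects")) {
  kind <- match.arg(kind)
  env <- if (kind == "image") ws$images else ws$objectsets
  if (!exists(name, envir = env, inherits = FALSE))
    stop(sprintf("no %s named '%s' in the workspace", kind, name))
  get(name, envir = env, inherits = FALSE)
}

#' Remove an image or object set from a workspace
#'
#' Removing an object set first severs every relationship link its members
#' hold, so no surviving object in any other set keeps a dangling
#' reference.
#'
#' @param ws a \code{\link{Workspace}}.
#' @param name stored name.
#' @param kind "image" or "objects".
#' @return \code{ws}, invisibly.
#' @export
removeItem <- function(ws, name, kind = c("image", "objects")) {
  kind <- match.arg(kind)
  env <- if (kind == "image") ws$images else ws$objectsets
  if (!exists(name, envir = env, inherits = FALSE))
    stop(sprintf("no %s named '%s' in the workspace", kind, name))
  if (kind == "objects") {
    set <- get(name, envir = env, inherits = FALSE)
    for (o in set$objects()) unlinkObject(o)
  }
  rm(list = name, envir = env)
  invisible(ws)
}
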