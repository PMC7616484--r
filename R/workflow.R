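#' Workflow parameters and module specifications
#'
#' A workflow is an ordered, serializable list of module invocations. Each
#' \code{ModuleSpec} names a registered module type, carries a display
#' nickname, a user enable flag and a list of typed parameters. Parameter
#' kinds distinguish plain values from the named image/object inputs and
#' outputs that the engine uses for validation and reactive enablement.
#' Each parameter also carries a \code{visible} flag marking it as part of
#' the simplified end-user view (the subset printed by
#' \code{\link{describeWorkflow}}).
#'
#' @name workflow-classes
NULL

.paramKinds <- c("text", "number", "boolean", "choice", "input-image",
                 "input-objects", "output-image", "output-objects",
                 "file-path")

#' Create a workflow parameter
#'
#' @param name parameter name.
#' @param kind one of text, number, boolean, choice, input-image,
#'   input-objects, output-image, output-objects, file-path.
#' @param value parameter value (scalar).
#' @param visible show this parameter in the simplified processing view?
#' @param choices for kind "choice", the allowed values.
#' @return A parameter (named list) for inclusion in a \code{ModuleSpec}.
#' @export
wfParam <- function(name, kind, value, visible = FALSE, choices = NULL) {
  kind <- match.arg(kind, .paramKinds)
  if (kind == "choice" && !is.null(choices) && !(value %in% choices))
    stop(sprintf("parameter '%s': value '%s' is not among the declared choices",
                 name, value))
  p <- list(name = name, kind = kind, value = value,
            visible = isTRUE(visible))
  if (!is.null(choices)) p$choices <- as.character(choices)
  p
}

#' @rdname workflow-classes
#' @slot moduleId registered module type name.
#' @slot nickname display name (also the target of skip-to jumps).
#' @slot enabled user enable flag.
#' @slot parameters list of parameters created with \code{\link{wfParam}}.
#' @export
setClass("ModuleSpec",
  representation(moduleId = "character", nickname = "character",
                 enabled = "logical", parameters = "list"),
  prototype(enabled = TRUE, parameters = list()))

#' Create a module specification
#'
#' @param moduleId registered module type name.
#' @param ... parameters created with \code{\link{wfParam}}.
#' @param nickname display name; defaults to the module id.
#' @param enabled user enable flag.
#' @return A \code{ModuleSpec}.
#' @export
moduleSpec <- function(moduleId, ..., nickname = moduleId, enabled = TRUE) {
  new("ModuleSpec", moduleId = moduleId, nickname = nickname,
      enabled = enabled, parameters = list(...))
}

#' @rdname workflow-classes
#' @slot modules ordered list of \code{ModuleSpec}.
#' @slot formatVersion serialization dialect version.
#' @export
setClass("Workflow",
  representation(modules = "list", formatVersion = "character"),
  prototype(modules = list(), formatVersion = "1"))

#' Create a workflow from module specifications
#' @param ... \code{ModuleSpec} objects, in execution order.
#' @return A \code{Workflow}.
#' @export
workflow <- function(...) {
  mods <- list(...)
  stopifnot(all(vapply(mods, is, TRUE, "ModuleSpec")))
  new("Workflow", modules = mods, formatVersion = "1")
}

setMethod("show", "ModuleSpec", function(object) {
  cat(sprintf("<ModuleSpec %s ('%s')%s, %d parameters>\n", object@moduleId,
              object@nickname, if (object@enabled) "" else " [disabled]",
              length(object@parameters)))
})

setMethod("show", "Workflow", function(object) {
  cat(sprintf("Workflow (format %s) with %d modules:\n", object@formatVersion,
              length(object@modules)))
  for (i in seq_along(object@modules)) {
    m <- object@modules[[i]]
    cat(sprintf("  %2d. %s ('%s')%s\n", i, m@moduleId, m@nickname,
                if (m@enabled) "" else " [disabled]"))
  }
})

#' Look up a parameter value in a module spec
#'
#' @param mod a \code{ModuleSpec}.
#' @param name parameter name.
#' @param default value returned when the parameter is absent.
#' @return The parameter's value.
#' @export
modParam <- function(mod, name, default = NULL) {
  for (p in mod@parameters) if (p$name == name) return(p$value)
  default
}

.paramsByKind <- function(mod, kinds) {
  vals <- character(0)
  for (p in mod@parameters)
    if (p$kind %in% kinds && is.character(p$value) && nzchar(p$value))
      vals <- c(vals, p$value)
  vals
}

## ---- module registry ----

.moduleRegistry <- new.env(parent = emptyenv())

#' Register a module type
#'
#' The registry is the extension point for third-party modules: any
#' function registered under an id becomes available to workflows. The
#' function is called as \code{fun(params, ws, seed)} where \code{params}
#' is a name-to-value list, \code{ws} the current \code{\link{Workspace}}
#' and \code{seed} the job seed; it may return
#' \code{list(action = "terminate")} or
#' \code{list(action = "skip_to", label = <nickname>)} to steer execution,
#' or anything else (ignored) to continue.
#'
#' @param id module type name.
#' @param fun module body.
#' @param description one-line description for \code{listModules}.
#' @return \code{id}, invisibly.
#' @export
registerModule <- function(id, fun, description = "") {
  stopifnot(is.function(fun))
  assign(id, list(fun = fun, description = description),
         envir = .moduleRegistry)
  invisible(id)
}

#' @rdname registerModule
#' @export
moduleExists <- function(id) exists(id, envir = .moduleRegistry,
                                    inherits = FALSE)

#' @rdname registerModule
#' @export
listModules <- function() {
  ids <- sort(ls(.moduleRegistry))
  data.frame(
    module_id = ids,
    description = vapply(ids, function(i)
      get(i, envir = .moduleRegistry)$description, ""),
    row.names = NULL)
}

.moduleFun <- function(id) {
  if (!moduleExists(id)) stop(sprintf("unknown module id '%s'", id))
  get(id, envir = .moduleRegistry)$fun
}

## ---- serialization (versioned JSON dialect, canonical key order) ----

.paramToList <- function(p) {
  out <- list(name = p$name, kind = p$kind, value = p$value,
              visible = p$visible)
  if (!is.null(p$choices)) out$choices <- as.list(p$choices)
  out
}

#' Serialize / deserialize workflows as text
#'
#' Workflows are stored as a versioned JSON document with a fixed key
#' order, so serialize-deserialize-serialize round trips are
#' byte-identical. The document records, per module: id, nickname, enabled
#' flag, and every parameter with its kind, value and visibility flag.
#'
#' @param wf a \code{Workflow}.
#' @return \code{serializeWorkflow}: a single character string (the JSON
#'   document). \code{deserializeWorkflow}: a \code{Workflow}; an unknown
#'   module id in the document is an error naming the offending id, and a
#'   malformed document is a parse error.
#' @examples
#' wf <- workflow(moduleSpec("remove_image",
#'   wfParam("input_image", "input-image", "Raw")))
#' txt <- serializeWorkflow(wf)
#' identical(serializeWorkflow(deserializeWorkflow(txt)), txt)
#' @export
serializeWorkflow <- function(wf) {
  doc <- list(
    format_version = wf@formatVersion,
    modules = lapply(wf@modules, function(m) list(
      module_id = m@moduleId,
      nickname = m@nickname,
      enabled = m@enabled,
      parameters = lapply(m@parameters, .paramToList)
    ))
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2,
                                digits = NA, null = "null"))
}

#' @rdname serializeWorkflow
#' @param text JSON text produced by \code{serializeWorkflow}.
#' @export
deserializeWorkflow <- function(text) {
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop(sprintf("malformed workflow document: %s",
                                 conditionMessage(e)), call. = FALSE))
  if (is.null(doc$format_version))
    stop("malformed workflow document: missing format_version")
  mods <- lapply(doc$modules, function(m) {
    if (is.null(m$module_id) || !moduleExists(m$module_id))
      stop(sprintf("unknown module id '%s' in workflow document",
                   if (is.null(m$module_id)) "<missing>" else m$module_id),
           call. = FALSE)
    params <- lapply(m$parameters, function(p)
      wfParam(p$name, p$kind, p$value, visible = isTRUE(p$visible),
              choices = if (is.null(p$choices)) NULL else unlist(p$choices)))
    new("ModuleSpec", moduleId = m$module_id,
        nickname = if (is.null(m$nickname)) m$module_id else m$nickname,
        enabled = isTRUE(m$enabled), parameters = params)
  })
  new("Workflow", modules = mods,
      formatVersion = as.character(doc$format_version))
}

#' Write / read a workflow file
#'
#' Convenience wrappers writing the serialized document to disk (the
#' ".wf.json" workflow file format).
#'
#' @param wf a \code{Workflow}.
#' @param path file path.
#' @return \code{readWorkflow}: a \code{Workflow}.
#' @export
writeWorkflow <- function(wf, path) {
  writeLines(serializeWorkflow(wf), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeWorkflow
#' @export
readWorkflow <- function(path) {
  if (!file.exists(path)) stop(sprintf("workflow file not found: %s", path))
  deserializeWorkflow(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
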