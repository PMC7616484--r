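#' Identified objects and object sets
#'
#' An \code{Obj} is one identified region: an integer id unique within its
#' set, the name of its owning class, a timepoint (0-based frame index), a
#' \code{\link{CoordinateStore}} holding its voxels (possibly empty for
#' purely linking objects such as tracks), a named measurement map, and
#' relationship links. Links come in two kinds: parent-child (one-to-many;
#' a child has at most one parent per parent class, but may have parents in
#' several classes) and partner (symmetric many-to-many). Children of one
#' object may themselves be parents of others, so grandparent-grandchild
#' relationships and beyond arise naturally and can be traversed with
#' \code{\link{resolveHierarchy}}.
#'
#' \code{Obj} and \code{ObjectSet} are reference objects: relationship
#' assignments mutate both ends in place, keeping the bidirectional links
#' consistent without copying.
#'
#' @field id integer id, unique within the owning set.
#' @field className name of the owning object set.
#' @field timepoint 0-based frame index.
#' @field store a \code{CoordinateStore} (may be empty).
#' @field measurements named list of numeric values (NA = missing).
#' @field parents,children,partners environments keyed by class name.
#' @export Obj
#' @exportClass Obj
Obj <- setRefClass("Obj",
  fields = list(
    id = "integer",
    className = "character",
    timepoint = "integer",
    store = "ANY",
    measurements = "list",
    parents = "environment",
    children = "environment",
    partners = "environment"
  ),
  methods = list(
    initialize = function(...) {
      initFields(id = 0L, className = "", timepoint = 0L,
                 store = emptyStore(), measurements = list(),
                 parents = new.env(parent = emptyenv()),
                 children = new.env(parent = emptyenv()),
                 partners = new.env(parent = emptyenv()))
      callSuper(...)
      parents <<- new.env(parent = emptyenv())
      children <<- new.env(parent = emptyenv())
      partners <<- new.env(parent = emptyenv())
      invisible(.self)
    },
    setMeasurement = function(name, value) {
      measurements[[name]] <<- as.numeric(value)
      invisible(.self)
    },
    getMeasurement = function(name) {
      if (is.null(measurements[[name]])) NA_real_ else measurements[[name]]
    },
    show = function() {
      cat(sprintf("<Obj %s #%d t=%d, %d voxels, %d measurements>\n",
                  className, id, timepoint, storeSize(store),
                  length(measurements)))
    }
  )
)

#' @rdname Obj-class
#' @field calibration shared \code{\link{SpatialCalibration}} of members.
#' @export ObjectSet
#' @exportClass ObjectSet
ObjectSet <- setRefClass("ObjectSet",
  fields = list(
    className = "character",
    calibration = "ANY",
    objs = "environment",
    nextId = "integer"
  ),
  methods = list(
    initialize = function(className = "objects",
                          calibration = SpatialCalibration(), ...) {
      initFields(className = className, calibration = calibration,
                 objs = new.env(parent = emptyenv()), nextId = 1L)
      callSuper(...)
      objs <<- new.env(parent = emptyenv())
      invisible(.self)
    },
    newObj = function(timepoint = 0L, store = emptyStore()) {
      "Create, register and return a fresh member with the next free id."
      o <- Obj$new()
      o$id <- nextId
      o$className <- className
      o$timepoint <- as.integer(timepoint)
      o$store <- store
      nextId <<- nextId + 1L
      assign(as.character(o$id), o, envir = objs)
      o
    },
    getObj = function(id) {
      key <- as.character(id)
      if (!exists(key, envir = objs, inherits = FALSE))
        stop(sprintf("no object with id %s in set '%s'", key, className))
      get(key, envir = objs, inherits = FALSE)
    },
    ids = function() sort(as.integer(ls(objs))),
    objects = function() lapply(ids(), function(i) getObj(i)),
    size = function() length(ls(objs)),
    removeObj = function(id) {
      "Remove one member, clearing all links to it from other objects."
      o <- getObj(id)
      unlinkObject(o)
      rm(list = as.character(id), envir = objs)
      invisible(.self)
    },
    show = function() {
      cat(sprintf("<ObjectSet '%s' with %d objects>\n", className, size()))
    }
  )
)

.envGet <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE))
    get(key, envir = env, inherits = FALSE) else NULL
}

.isAncestor <- function(candidate, obj) {
  # TRUE if `candidate` is reachable from `obj` by following parent links
  stack <- list(obj)
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (cls in ls(cur$parents)) {
      p <- .envGet(cur$parents, cls)
      if (is.null(p)) next
      if (identical(p, candidate)) return(TRUE)
      stack[[length(stack) + 1]] <- p
    }
  }
  FALSE
}

#' Assign a parent-child relationship
#'
#' Sets \code{parent} as the parent of \code{child} for the parent's class.
#' A child holds at most one parent per class, so any previous parent of
#' that class is unlinked first; both ends of the link are updated.
#' Self-parenting and any assignment that would make an object its own
#' ancestor raise an error (parent graphs stay acyclic).
#'
#' @param child,parent \code{Obj} references.
#' @return \code{child}, invisibly.
#' @export
assignParent <- function(child, parent) {
  if (identical(child, parent))
    stop("an object cannot be its own parent")
  if (.isAncestor(child, parent))
    stop("assignment would create an ancestry cycle")
  cls <- parent$className
  old <- .envGet(child$parents, cls)
  if (!is.null(old)) .dropChild(old, child)
  assign(cls, parent, envir = child$parents)
  kids <- .envGet(parent$children, child$className)
  if (is.null(kids)) kids <- list()
  kids[[as.character(child$id)]] <- child
  assign(child$className, kids, envir = parent$children)
  invisible(child)
}

.dropChild <- function(parent, child) {
  kids <- .envGet(parent$children, child$className)
  if (!is.null(kids)) {
    kids[[as.character(child$id)]] <- NULL
    assign(child$className, kids, envir = parent$children)
  }
}

#' Remove a parent link by class
#'
#' @param child an \code{Obj}.
#' @param parentClass class name of the parent to unlink.
#' @return \code{child}, invisibly.
#' @export
removeParent <- function(child, parentClass) {
  p <- .envGet(child$parents, parentClass)
  if (!is.null(p)) {
    .dropChild(p, child)
    rm(list = parentClass, envir = child$parents)
  }
  invisible(child)
}

#' Assign a symmetric partner relationship
#'
#' Each object lists the other under the partner's class name. The
#' operation is idempotent; partnering an object with itself is an error.
#'
#' @param a,b distinct \code{Obj} references.
#' @return \code{a}, invisibly.
#' @export
assignPartners <- function(a, b) {
  if (identical(a, b)) stop("an object cannot be its own partner")
  .addPartner(a, b)
  .addPartner(b, a)
  invisible(a)
}

.addPartner <- function(a, b) {
  ps <- .envGet(a$partners, b$className)
  if (is.null(ps)) ps <- list()
  ps[[as.character(b$id)]] <- b
  assign(b$className, ps, envir = a$partners)
}

#' Remove a partner relationship (both ends)
#' @param a,b \code{Obj} references.
#' @return \code{a}, invisibly.
#' @export
removePartners <- function(a, b) {
  .dropPartner(a, b)
  .dropPartner(b, a)
  invisible(a)
}

.dropPartner <- function(a, b) {
  ps <- .envGet(a$partners, b$className)
  if (!is.null(ps)) {
    ps[[as.character(b$id)]] <- NULL
    assign(b$className, ps, envir = a$partners)
  }
}

#' Clear every link touching an object
#'
#' Used when an object (or its whole set) is removed so no surviving object
#' holds a dangling reference.
#'
#' @param obj an \code{Obj}.
#' @return \code{obj}, invisibly.
#' @export
unlinkObject <- function(obj) {
  for (cls in ls(obj$parents)) removeParent(obj, cls)
  for (cls in ls(obj$children)) {
    for (child in .envGet(obj$children, cls)) removeParent(child, obj$className)
  }
  for (cls in ls(obj$partners)) {
    for (p in .envGet(obj$partners, cls)) removePartners(obj, p)
  }
  invisible(obj)
}

#' Accessors for relationship links
#'
#' \code{getParent} returns the parent of the given class or NULL;
#' \code{getChildren}/\code{getPartners} return (possibly empty) lists of
#' \code{Obj}, sorted by id.
#'
#' @param obj an \code{Obj}.
#' @param className relationship class name.
#' @name relationship-accessors
#' @export
getParent <- function(obj, className) .envGet(obj$parents, className)

#' @rdname relationship-accessors
#' @export
getChildren <- function(obj, className) {
  kids <- .envGet(obj$children, className)
  if (is.null(kids)) return(list())
  unname(kids[order(as.integer(names(kids)))])
}

#' @rdname relationship-accessors
#' @export
getPartners <- function(obj, className) {
  ps <- .envGet(obj$partners, className)
  if (is.null(ps)) return(list())
  unname(ps[order(as.integer(names(ps)))])
}

#' Traverse a relationship hierarchy
#'
#' Follows \code{path} hop by hop from \code{obj}. At each hop the class
#' name is looked up first among parent links, then among child links, of
#' the objects reached so far; parent hops contribute at most one object
#' each, child hops contribute sets. An empty path returns the object
#' itself. A class name that is neither a parent nor a child class of any
#' current object is a relationship error.
#'
#' @param obj an \code{Obj}.
#' @param path character vector of class names.
#' @return \code{obj} for an empty path; otherwise a list of \code{Obj}
#'   (de-duplicated, sorted by class then id). Counting over the result
#'   supports measurements such as per-parent child counts.
#' @export
resolveHierarchy <- function(obj, path) {
  if (!length(path)) return(obj)
  current <- list(obj)
  for (cls in path) {
    nxt <- list()
    known <- FALSE
    for (o in current) {
      if (!is.null(.envGet(o$parents, cls)) ||
          exists(cls, envir = o$parents, inherits = FALSE)) {
        known <- TRUE
        p <- .envGet(o$parents, cls)
        if (!is.null(p)) nxt[[paste0(cls, "#", p$id)]] <- p
      } else if (exists(cls, envir = o$children, inherits = FALSE)) {
        known <- TRUE
        for (k in .envGet(o$children, cls))
          nxt[[paste0(cls, "#", k$id)]] <- k
      }
    }
    if (!known)
      stop(sprintf("class '%s' is not a registered relationship of the current objects", cls))
    current <- unname(nxt[order(names(nxt))])
  }
  current
}

#' Object centroid in pixel and calibrated units
#'
#' Arithmetic mean of the voxel coordinates. An empty store (e.g. a track
#' linking object) yields missing values rather than an error.
#'
#' @param obj an \code{Obj}.
#' @param calibration optional \code{\link{SpatialCalibration}}; when
#'   given, calibrated coordinates are included.
#' @return Named numeric vector \code{x, y, z} (pixels), plus
#'   \code{x_cal, y_cal, z_cal} when a calibration is supplied.
#' @export
objectCentroid <- function(obj, calibration = NULL) {
  v <- storeVoxels(obj$store)
  if (!nrow(v)) {
    out <- c(x = NA_real_, y = NA_real_, z = NA_real_)
  } else {
    out <- c(x = mean(v[, 1]), y = mean(v[, 2]), z = mean(v[, 3]))
  }
  if (!is.null(calibration)) {
    out <- c(out, x_cal = unname(out["x"]) * calibration@dx,
             y_cal = unname(out["y"]) * calibration@dy,
             z_cal = unname(out["z"]) * calibration@dz)
  }
  out
}

#' Audit relationship consistency over object sets
#'
#' Checks, across all members of the supplied sets: bidirectional
#' parent-child consistency (A listing B as child implies B lists A as its
#' parent for A's class, and vice versa), partner symmetry, the
#' one-parent-per-class rule (structural), and acyclicity of the parent
#' graph.
#'
#' @param sets list of \code{ObjectSet}.
#' @return TRUE if consistent, otherwise a character message describing the
#'   first violation found.
#' @export
auditRelationships <- function(sets) {
  allObjs <- unlist(lapply(sets, function(s) s$objects()), use.names = FALSE)
  for (o in allObjs) {
    for (cls in ls(o$parents)) {
      p <- .envGet(o$parents, cls)
      if (is.null(p)) next
      if (p$className != cls)
        return(sprintf("%s#%d parent stored under wrong class", o$className, o$id))
      kids <- .envGet(p$children, o$className)
      if (is.null(kids) || !identical(kids[[as.character(o$id)]], o))
        return(sprintf("%s#%d not listed among children of its parent %s#%d",
                       o$className, o$id, p$className, p$id))
    }
    for (cls in ls(o$children)) {
      for (k in .envGet(o$children, cls)) {
        back <- .envGet(k$parents, o$className)
        if (!identical(back, o))
          return(sprintf("%s#%d child %s#%d does not point back",
                         o$className, o$id, k$className, k$id))
      }
    }
    for (cls in ls(o$partners)) {
      for (p in .envGet(o$partners, cls)) {
        back <- .envGet(p$partners, o$className)
        if (is.null(back) || is.null(back[[as.character(o$id)]]))
          return(sprintf("partner link %s#%d -> %s#%d not symmetric",
                         o$className, o$id, p$className, p$id))
      }
    }
    if (.isAncestor(o, o))
      return(sprintf("%s#%d is its own ancestor", o$className, o$id))
  }
  TRUE
}
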