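#' Per-image summary statistics of object measurements
#'
#' For every object set in the workspace and every measurement its members
#' carry, computes mean, min, max, sample standard deviation (n - 1
#' denominator), sum and count over the workspace. Empty sets yield a
#' count of 0 with missing statistics; a single value yields a missing
#' standard deviation.
#'
#' @param ws a \code{\link{Workspace}}.
#' @return data.frame with columns object_set, measurement, mean, min,
#'   max, sd, sum, count.
#' @export
summariseImageMeasurements <- function(ws) {
  rows <- list()
  for (setName in ws$objectSetNames()) {
    set <- getItem(ws, setName, "objects")
    members <- set$objects()
    measNames <- sort(unique(unlist(lapply(members, function(o)
      names(o$measurements)))))
    if (!length(members)) {
      rows[[length(rows) + 1]] <- data.frame(
        object_set = setName, measurement = NA_character_,
        mean = NA_real_, min = NA_real_, max = NA_real_, sd = NA_real_,
        sum = NA_real_, count = 0L)
      next
    }
    for (mn in measNames) {
      vals <- vapply(members, function(o) o$getMeasurement(mn), 0)
      vals <- vals[!is.na(vals)]
      n <- length(vals)
      rows[[length(rows) + 1]] <- data.frame(
        object_set = setName, measurement = mn,
        mean = if (n) mean(vals) else NA_real_,
        min = if (n) min(vals) else NA_real_,
        max = if (n) max(vals) else NA_real_,
        sd = if (n >= 2) sd(vals) else NA_real_,
        sum = if (n) sum(vals) else NA_real_,
        count = n)
    }
  }
  if (!length(rows))
    return(data.frame(object_set = character(0), measurement = character(0),
                      mean = numeric(0), min = numeric(0), max = numeric(0),
                      sd = numeric(0), sum = numeric(0), count = integer(0)))
  do.call(rbind, rows)
}

.fmtNum <- function(x) {
  ifelse(is.na(x), NA_character_,
         vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                      trim = TRUE), ""))
}

.metaCols <- function(ws) {
  c(job_index = as.character(ws$metadata$jobIndex),
    filename = ws$metadata$filename,
    folder = ws$metadata$folder,
    series = ws$metadata$seriesName)
}

# one row per object: metadata, id, timepoint, measurements (sorted),
# parent ids per parent class (sorted), partner counts per partner class
.objectSheet <- function(workspaces, className) {
  measNames <- character(0); parentCls <- character(0); partnerCls <- character(0)
  for (ws in workspaces) {
    if (!(className %in% ws$objectSetNames())) next
    for (o in getItem(ws, className, "objects")$objects()) {
      measNames <- union(measNames, names(o$measurements))
      parentCls <- union(parentCls, ls(o$parents))
      partnerCls <- union(partnerCls, ls(o$partners))
    }
  }
  measNames <- sort(measNames); parentCls <- sort(parentCls)
  partnerCls <- sort(partnerCls)
  header <- c("job_index", "filename", "folder", "series", "object_id",
              "timepoint", measNames,
              if (length(parentCls)) paste0("PARENT_", parentCls, "_ID"),
              if (length(partnerCls)) paste0("N_PARTNERS_", partnerCls))
  rows <- list()
  for (ws in workspaces) {
    if (!(className %in% ws$objectSetNames())) next
    meta <- .metaCols(ws)
    for (o in getItem(ws, className, "objects")$objects()) {
      mvals <- .fmtNum(vapply(o$measurements[measNames], function(v)
        if (is.null(v)) NA_real_ else v, 0, USE.NAMES = FALSE))
      pvals <- vapply(parentCls, function(cl) {
        p <- getParent(o, cl)
        if (is.null(p)) NA_character_ else as.character(p$id)
      }, "")
      qvals <- vapply(partnerCls, function(cl)
        as.character(length(getPartners(o, cl))), "")
      rows[[length(rows) + 1]] <-
        c(meta, as.character(o$id), as.character(o$timepoint),
          mvals, pvals, qvals)
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), 0, length(header))
  rbind(header, m)
}

.imageSheet <- function(workspaces) {
  measNames <- sort(unique(unlist(lapply(workspaces, function(ws)
    unlist(lapply(ws$imageNames(), function(nm)
      names(getItem(ws, nm, "image")$measurements)))))))
  header <- c("job_index", "filename", "folder", "series", "image", measNames)
  rows <- list()
  for (ws in workspaces) {
    meta <- .metaCols(ws)
    for (nm in ws$imageNames()) {
      img <- getItem(ws, nm, "image")
      vals <- .fmtNum(vapply(measNames, function(mn) img$getMeasurement(mn), 0))
      rows[[length(rows) + 1]] <- c(meta, nm, vals)
    }
  }
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), 0, length(header))
  rbind(header, m)
}

.summarySheet <- function(workspaces) {
  rows <- list()
  for (ws in workspaces) {
    s <- summariseImageMeasurements(ws)
    if (!nrow(s)) next
    meta <- .metaCols(ws)
    for (i in seq_len(nrow(s))) {
      rows[[length(rows) + 1]] <- c(
        meta, s$object_set[i],
        if (is.na(s$measurement[i])) "" else s$measurement[i],
        .fmtNum(c(s$mean[i], s$min[i], s$max[i], s$sd[i], s$sum[i])),
        as.character(s$count[i]))
    }
  }
  header <- c("job_index", "filename", "folder", "series", "object_set",
              "measurement", "mean", "min", "max", "sd", "sum", "count")
  m <- if (length(rows)) do.call(rbind, rows) else
    matrix(character(0), 0, length(header))
  rbind(header, m)
}

.buildWorkbook <- function(workspaces, wf, includeSummary) {
  sheets <- list(Images = .imageSheet(workspaces))
  classes <- sort(unique(unlist(lapply(workspaces, function(ws)
    ws$objectSetNames()))))
  for (cl in classes) sheets[[cl]] <- .objectSheet(workspaces, cl)
  if (includeSummary) sheets[["Summary"]] <- .summarySheet(workspaces)
  cfg <- strsplit(serializeWorkflow(wf), "\n", fixed = TRUE)[[1]]
  sheets[["Configuration"]] <- matrix(cfg, ncol = 1)
  sheets
}

#' Export measurements to xlsx with embedded provenance
#'
#' Writes the image-level sheet (one row per workspace per image with job
#' metadata columns), one sheet per object class (one row per object: job
#' metadata, id, timepoint, measurements sorted by name, parent ids per
#' parent class, partner counts per partner class), optionally a summary
#' sheet (\code{\link{summariseImageMeasurements}} per workspace) and a
#' "Configuration" sheet holding the serialized workflow text verbatim, so
#' the exact workflow can be recovered from the results file alone (see
#' \code{\link{recoverWorkflow}}). Missing values become empty cells.
#'
#' @param workspaces list of \code{\link{Workspace}} (at least one).
#' @param wf the \code{Workflow} that produced them.
#' @param path output path. In "combined" mode this is the single .xlsx
#'   file; in "per-file" mode it is a directory receiving one workbook per
#'   workspace, named after each job's input file.
#' @param mode "combined" or "per-file".
#' @param includeSummary add the per-image summary statistics sheet?
#' @param csvMirror also write each sheet as a CSV next to the workbook
#'   (for headless diffing)?
#' @return Character vector of workbook paths written, invisibly.
#' @export
exportResults <- function(workspaces, wf, path, mode = c("combined", "per-file"),
                          includeSummary = TRUE, csvMirror = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(workspaces) >= 1)
  writeOne <- function(wss, p) {
    sheets <- .buildWorkbook(wss, wf, includeSummary)
    writeXlsx(sheets, p)
    if (csvMirror) {
      for (nm in names(sheets)) {
        utils::write.table(sheets[[nm]],
                           paste0(tools::file_path_sans_ext(p), "_", nm, ".csv"),
                           sep = ",", row.names = FALSE, col.names = FALSE,
                           na = "")
      }
    }
    p
  }
  if (mode == "combined") {
    return(invisible(writeOne(workspaces, path)))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  for (ws in workspaces) {
    base <- ws$metadata$filename
    base <- if (nzchar(base)) tools::file_path_sans_ext(base)
    else sprintf("job%03d", ws$metadata$jobIndex)
    out <- c(out, writeOne(list(ws), file.path(path, paste0(base, ".xlsx"))))
  }
  invisible(out)
}

#' Recover the workflow embedded in an exported workbook
#'
#' Reads the "Configuration" sheet and deserializes the stored workflow
#' text — the provenance path for re-running an analysis when the original
#' workflow file has been lost.
#'
#' @param path .xlsx file written by \code{\link{exportResults}}.
#' @return A \code{Workflow}.
#' @export
recoverWorkflow <- function(path) {
  m <- readXlsxSheet(path, "Configuration")
  deserializeWorkflow(paste(m[, 1], collapse = "\n"))
}
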