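#' Workflow validation
#'
#' Structural checks performed before any module runs, so unsatisfiable
#' references are reported up front rather than mid-run: every module id
#' must be registered, and every named image/object input must be produced
#' (or updated in place) by some earlier module in the list.
#'
#' @param wf a \code{Workflow}.
#' @return Character vector of problems; empty when the workflow is valid.
#' @export
validateWorkflow <- function(wf) {
  problems <- character(0)
  produced <- character(0)
  for (i in seq_along(wf@modules)) {
    m <- wf@modules[[i]]
    if (!moduleExists(m@moduleId)) {
      problems <- c(problems,
                    sprintf("module %d: unknown module id '%s'", i, m@moduleId))
      next
    }
    for (nm in .paramsByKind(m, c("input-image", "input-objects"))) {
      if (!(nm %in% produced))
        problems <- c(problems, sprintf(
          "module %d (%s): input '%s' is not produced by any earlier module",
          i, m@nickname, nm))
    }
    produced <- union(produced,
                      .paramsByKind(m, c("output-image", "output-objects")))
  }
  problems
}

#' Effective enablement under reactive dependencies
#'
#' A module is effectively enabled iff its user flag is on and every named
#' image/object input is produced by an effectively enabled earlier module.
#' Disabling one module therefore automatically disables exactly the
#' downstream modules whose input chains it breaks; re-enabling restores
#' them (the computation is a pure function of the user flags).
#'
#' @param wf a \code{Workflow}.
#' @return Logical vector, one flag per module.
#' @export
effectiveEnablement <- function(wf) {
  n <- length(wf@modules)
  eff <- logical(n)
  available <- character(0)
  for (i in seq_len(n)) {
    m <- wf@modules[[i]]
    inputs <- .paramsByKind(m, c("input-image", "input-objects"))
    eff[i] <- m@enabled && all(inputs %in% available)
    if (eff[i])
      available <- union(available,
                         .paramsByKind(m, c("output-image", "output-objects")))
  }
  eff
}

#' Evaluate a workflow-handling condition
#'
#' Conditions compare an object-set count or an image measurement against a
#' threshold and, when the predicate holds, direct the engine to terminate
#' the run or skip forward to a labelled module. Referencing a missing
#' workspace item is an error (surfaced as a job failure by the engine).
#'
#' @param cond list with fields \code{target} ("objects" or "image"),
#'   \code{name} (workspace item name), \code{measurement} (image
#'   measurement name; ignored for object counts), \code{operator} (one of
#'   "<", "<=", ">", ">=", "=="), \code{threshold} (numeric), \code{action}
#'   ("terminate" or "skip_to") and, for skip_to, \code{label} (nickname of
#'   a later module).
#' @param ws a \code{\link{Workspace}}.
#' @return \code{list(action = "continue")}, \code{list(action =
#'   "terminate")} or \code{list(action = "skip_to", label = ...)}.
#' @export
evaluateCondition <- function(cond, ws) {
  value <- if (cond$target == "objects") {
    getItem(ws, cond$name, "objects")$size()
  } else {
    img <- getItem(ws, cond$name, "image")
    v <- img$getMeasurement(cond$measurement)
    if (is.na(v))
      stop(sprintf("image '%s' has no measurement '%s'", cond$name,
                   cond$measurement))
    v
  }
  hit <- switch(cond$operator,
    "<" = value < cond$threshold,
    "<=" = value <= cond$threshold,
    ">" = value > cond$threshold,
    ">=" = value >= cond$threshold,
    "==" = value == cond$threshold,
    stop(sprintf("unknown operator '%s'", cond$operator)))
  if (!hit) return(list(action = "continue"))
  if (cond$action == "terminate") return(list(action = "terminate"))
  if (cond$action == "skip_to")
    return(list(action = "skip_to", label = cond$label))
  list(action = "continue")
}

#' Outcome of one workflow run
#'
#' @slot status overall job status: "completed", "terminated" or "failed".
#' @slot moduleStatus per-module status, one of "executed", "skipped",
#'   "disabled", "failed"; covers every module exactly once.
#' @slot log message list collected during the run.
#' @export
setClass("RunOutcome",
  representation(status = "character", moduleStatus = "character",
                 log = "character"),
  prototype(status = "completed", moduleStatus = character(0),
            log = character(0)))

setMethod("show", "RunOutcome", function(object) {
  cat(sprintf("<RunOutcome %s: %s>\n", object@status,
              paste(object@moduleStatus, collapse = ", ")))
})

#' Execute a workflow over a workspace
#'
#' Runs the effectively enabled modules in list order. Workflow-handling
#' modules may terminate the run (remaining modules are marked skipped) or
#' skip forward to a labelled module (intermediate modules are marked
#' skipped; jumps are forward-only). A module raising an error aborts the
#' job: its status is "failed", the cause is logged, the remaining modules
#' are marked skipped and the overall status is "failed". Execution is
#' deterministic: every stochastic module receives the job seed.
#'
#' @param wf a \code{Workflow}; must validate (see
#'   \code{\link{validateWorkflow}}).
#' @param ws a \code{\link{Workspace}}.
#' @param seed integer seed forwarded to stochastic modules.
#' @return A \code{RunOutcome}.
#' @export
executeWorkflow <- function(wf, ws, seed = 42L) {
  problems <- validateWorkflow(wf)
  if (length(problems))
    stop(paste(c("workflow failed validation:", problems), collapse = "\n  "))
  n <- length(wf@modules)
  eff <- effectiveEnablement(wf)
  status <- ifelse(eff, "pending", "disabled")
  log <- character(0)
  overall <- "completed"
  i <- 1L
  while (i <= n) {
    if (status[i] != "pending") {
      i <- i + 1L
      next
    }
    m <- wf@modules[[i]]
    params <- setNames(lapply(m@parameters, `[[`, "value"),
                       vapply(m@parameters, `[[`, "", "name"))
    res <- tryCatch(
      .moduleFun(m@moduleId)(params, ws, seed),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "moduleError"))
    if (inherits(res, "moduleError")) {
      status[i] <- "failed"
      log <- c(log, sprintf("module %d (%s) failed: %s", i, m@nickname,
                            res$message))
      status[status == "pending"] <- "skipped"
      overall <- "failed"
      break
    }
    status[i] <- "executed"
    if (is.list(res) && !is.null(res$action)) {
      if (res$action == "terminate") {
        status[status == "pending"] <- "skipped"
        overall <- "terminated"
        log <- c(log, sprintf("module %d (%s): terminated workflow",
                              i, m@nickname))
        break
      }
      if (res$action == "skip_to") {
        target <- which(vapply(wf@modules, slot, "", "nickname") == res$label)
        target <- target[target > i]
        if (!length(target)) {
          status[status == "pending"] <- "skipped"
          overall <- "failed"
          log <- c(log, sprintf(
            "module %d (%s): skip_to label '%s' not found later in workflow",
            i, m@nickname, res$label))
          break
        }
        if (target[1] > i + 1L)
          status[(i + 1L):(target[1] - 1L)][
            status[(i + 1L):(target[1] - 1L)] == "pending"] <- "skipped"
        log <- c(log, sprintf("module %d (%s): skipped to '%s'",
                              i, m@nickname, res$label))
      }
    }
    i <- i + 1L
  }
  status[status == "pending"] <- "skipped"
  new("RunOutcome", status = overall, moduleStatus = status, log = log)
}

#' Describe a workflow's processing view
#'
#' Prints the module list with enablement and, for each module, the subset
#' of parameters flagged visible — the text rendering of the simplified
#' end-user view.
#'
#' @param wf a \code{Workflow}.
#' @param visibleOnly show only parameters flagged visible?
#' @return A character vector of lines, invisibly; also printed.
#' @export
describeWorkflow <- function(wf, visibleOnly = TRUE) {
  eff <- effectiveEnablement(wf)
  lines <- sprintf("Workflow (format %s), %d modules", wf@formatVersion,
                   length(wf@modules))
  for (i in seq_along(wf@modules)) {
    m <- wf@modules[[i]]
    state <- if (!m@enabled) "disabled"
    else if (!eff[i]) "disabled (upstream)" else "enabled"
    lines <- c(lines, sprintf("%2d. %s ('%s') [%s]", i, m@moduleId,
                              m@nickname, state))
    for (p in m@parameters) {
      if (visibleOnly && !isTRUE(p$visible)) next
      lines <- c(lines, sprintf("      %s (%s) = %s%s", p$name, p$kind,
                                format(p$value),
                                if (isTRUE(p$visible)) " [visible]" else ""))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
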