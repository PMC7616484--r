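#' Discover jobs under a folder tree
#'
#' Recursively scans \code{root} for files with an allowed extension and
#' applies the name filters conjunctively (zero filters accept
#' everything). Ordering is deterministic (lexicographic full path). A
#' single-file root yields exactly one job.
#'
#' @param root folder (or single file) to scan; missing paths are an
#'   error.
#' @param filters list of filters, each
#'   \code{list(target = "filename"|"folder"|"series", kind =
#'   "contains"|"not-contains"|"matches-pattern", value = <string>)}.
#' @param extensions allowed file extensions (case-insensitive).
#' @return Character vector of file paths, one per job, in stable order.
#' @export
discoverJobs <- function(root, filters = list(),
                         extensions = c(".tif", ".tiff")) {
  if (!file.exists(root)) stop(sprintf("input path does not exist: %s", root))
  files <- if (dir.exists(root)) {
    sort(list.files(root, recursive = TRUE, full.names = TRUE))
  } else root
  ext <- tolower(paste0(".", tools::file_ext(files)))
  files <- files[ext %in% tolower(extensions)]
  keep <- vapply(files, function(f) {
    for (fl in filters) {
      subject <- switch(fl$target,
        filename = basename(f),
        folder = dirname(f),
        series = "",
        stop(sprintf("unknown filter target '%s'", fl$target)))
      hit <- switch(fl$kind,
        contains = grepl(fl$value, subject, fixed = TRUE),
        `not-contains` = !grepl(fl$value, subject, fixed = TRUE),
        `matches-pattern` = grepl(fl$value, subject),
        stop(sprintf("unknown filter kind '%s'", fl$kind)))
      if (!hit) return(FALSE)
    }
    TRUE
  }, TRUE)
  unname(files[keep])
}

#' Outcome of a batch run
#'
#' @slot outcomes list of per-job \code{\link{RunOutcome}}, named by input
#'   path.
#' @slot counts named integer vector: completed, terminated, failed.
#' @slot outputs paths of the workbooks written.
#' @export
setClass("BatchReport",
  representation(outcomes = "list", counts = "integer", outputs = "character"))

setMethod("show", "BatchReport", function(object) {
  cat(sprintf("<BatchReport: %d completed, %d terminated, %d failed; %d output file(s)>\n",
              object@counts["completed"], object@counts["terminated"],
              object@counts["failed"], length(object@outputs)))
})

#' Run a workflow over a batch of jobs
#'
#' Each job runs in a fresh, isolated workspace; a failing job is recorded
#' in the report and the batch continues. After all jobs, results from the
#' non-failed workspaces are exported — once in combined mode, or one
#' workbook per job in per-file mode. With an empty job list a warning is
#' issued and no workbook is written.
#'
#' @param wf a validated \code{Workflow}.
#' @param jobs character vector of input file paths (see
#'   \code{\link{discoverJobs}}).
#' @param outputPath workbook path (combined) or directory (per-file).
#' @param mode "combined" or "per-file".
#' @param seed integer job seed forwarded to every workflow run.
#' @param includeSummary,csvMirror forwarded to
#'   \code{\link{exportResults}}.
#' @return A \code{BatchReport}.
#' @export
runBatch <- function(wf, jobs, outputPath, mode = c("combined", "per-file"),
                     seed = 42L, includeSummary = TRUE, csvMirror = FALSE) {
  mode <- match.arg(mode)
  problems <- validateWorkflow(wf)
  if (length(problems))
    stop(paste(c("workflow failed validation:", problems), collapse = "\n  "))
  if (!length(jobs)) {
    warning("no jobs to process; no workbook written")
    return(new("BatchReport", outcomes = list(),
               counts = c(completed = 0L, terminated = 0L, failed = 0L),
               outputs = character(0)))
  }
  outcomes <- list()
  workspaces <- list()
  for (i in seq_along(jobs)) {
    ws <- newWorkspace(sourcePath = jobs[i], jobIndex = i)
    out <- tryCatch(executeWorkflow(wf, ws, seed = seed),
                    error = function(e)
                      new("RunOutcome", status = "failed",
                          moduleStatus = rep("skipped",
                                             length(wf@modules)),
                          log = conditionMessage(e)))
    outcomes[[jobs[i]]] <- out
    if (out@status != "failed") workspaces[[length(workspaces) + 1]] <- ws
  }
  statuses <- vapply(outcomes, slot, "", "status")
  counts <- c(completed = sum(statuses == "completed"),
              terminated = sum(statuses == "terminated"),
              failed = sum(statuses == "failed"))
  outputs <- character(0)
  if (length(workspaces)) {
    outputs <- exportResults(workspaces, wf, outputPath, mode = mode,
                             includeSummary = includeSummary,
                             csvMirror = csvMirror)
  }
  new("BatchReport", outcomes = outcomes, counts = counts,
      outputs = as.character(outputs))
}
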