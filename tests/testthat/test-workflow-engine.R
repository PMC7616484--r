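chainWorkflow <- function(enabled = c(TRUE, TRUE, TRUE)) {
  registerNoopModules()
  workflow(
    moduleSpec("noop_producer",
               wfParam("output_image", "output-image", "Raw"),
               nickname = "Load", enabled = enabled[1]),
    moduleSpec("noop_transform",
               wfParam("input_image1", "input-image", "Raw"),
               wfParam("output_image", "output-image", "Binary"),
               nickname = "Threshold", enabled = enabled[2]),
    moduleSpec("noop_transform",
               wfParam("input_image1", "input-image", "Binary"),
               wfParam("output_image", "output-image", "Objects"),
               nickname = "Identify", enabled = enabled[3]))
}

test_that("disabling a module reactively disables its dependents", {
  expect_equal(effectiveEnablement(chainWorkflow()), c(TRUE, TRUE, TRUE))
  # disable the middle module: the consumer goes down with it
  expect_equal(effectiveEnablement(chainWorkflow(c(TRUE, FALSE, TRUE))),
               c(TRUE, FALSE, FALSE))
  # disabling a module nothing consumes affects only itself
  expect_equal(effectiveEnablement(chainWorkflow(c(TRUE, TRUE, FALSE))),
               c(TRUE, TRUE, FALSE))
  # re-enabling restores the original state (involution)
  expect_equal(effectiveEnablement(chainWorkflow()), c(TRUE, TRUE, TRUE))
})

test_that("reactivity is monotone and exact on random workflows", {
  for (seed in 1:25) {
    wf <- randomWorkflow(nModules = sample(4:9, 1), seed = seed)
    base <- effectiveEnablement(wf)
    # enabling any disabled module never effectively disables another
    n <- length(wf@modules)
    off <- sample(n, 1)
    wf2 <- wf; wf2@modules[[off]]@enabled <- FALSE
    eff2 <- effectiveEnablement(wf2)
    expect_true(all(eff2[-off] <= base[-off]))
    # exactly the modules with a broken input chain go down: recompute by
    # independent reachability over the dependency edges
    avail <- character(0)
    expected <- logical(n)
    for (i in seq_len(n)) {
      m <- wf2@modules[[i]]
      ins <- vapply(Filter(function(p) p$kind == "input-image", m@parameters),
                    `[[`, "", "value")
      expected[i] <- m@enabled && all(ins %in% avail)
      if (expected[i])
        avail <- c(avail, vapply(Filter(function(p) p$kind == "output-image",
                                        m@parameters), `[[`, "", "value"))
    }
    expect_equal(eff2, expected)
  }
})

test_that("validation reports unsatisfiable inputs and unknown modules", {
  registerNoopModules()
  wf <- workflow(
    moduleSpec("noop_transform",
               wfParam("input_image1", "input-image", "Missing"),
               wfParam("output_image", "output-image", "Out")))
  expect_match(validateWorkflow(wf), "not produced by any earlier module")
  wf2 <- new("Workflow", modules = list(
    new("ModuleSpec", moduleId = "no_such_module", nickname = "x",
        enabled = TRUE, parameters = list())), formatVersion = "1")
  expect_match(validateWorkflow(wf2), "unknown module id")
  expect_error(executeWorkflow(wf, newWorkspace()), "failed validation")
})

test_that("serialization round trips are byte-identical and typed", {
  registerNoopModules()
  wf <- workflow(
    moduleSpec("noop_producer",
               wfParam("output_image", "output-image", "Raw"),
               wfParam("sigma", "number", 2.5, visible = TRUE),
               wfParam("mode", "choice", "fast", choices = c("fast", "slow")),
               nickname = "Producer"),
    moduleSpec("noop_transform",
               wfParam("input_image1", "input-image", "Raw"),
               wfParam("output_image", "output-image", "Out"),
               enabled = FALSE))
  txt <- serializeWorkflow(wf)
  wf2 <- deserializeWorkflow(txt)
  expect_identical(serializeWorkflow(wf2), txt)
  # flags survive the round trip
  expect_true(wf2@modules[[1]]@parameters[[2]]$visible)
  expect_false(wf2@modules[[2]]@enabled)
  expect_equal(modParam(wf2@modules[[1]], "sigma"), 2.5)

  # unknown module id on read names the offender; malformed text errors
  bad <- sub("noop_producer", "martian_module", txt, fixed = TRUE)
  expect_error(deserializeWorkflow(bad), "martian_module")
  expect_error(deserializeWorkflow("{not json"), "malformed")
})

test_that("conditions drive terminate, skip and continue", {
  ws <- newWorkspace()
  putItem(ws, ObjectSet$new(className = "Nuclei"), "create")
  cond <- list(target = "objects", name = "Nuclei", operator = "==",
               threshold = 0, action = "terminate")
  expect_equal(evaluateCondition(cond, ws)$action, "terminate")
  getItem(ws, "Nuclei", "objects")$newObj()
  expect_equal(evaluateCondition(cond, ws)$action, "continue")
  cond2 <- list(target = "objects", name = "Nuclei", operator = ">=",
                threshold = 1, action = "skip_to", label = "Export")
  expect_equal(evaluateCondition(cond2, ws),
               list(action = "skip_to", label = "Export"))
  expect_error(evaluateCondition(list(target = "objects", name = "Ghost",
                                      operator = "==", threshold = 0,
                                      action = "terminate"), ws), "no objects")
})

test_that("execution honours terminate, skip_to and failure statuses", {
  registerNoopModules()
  if (!moduleExists("always_terminate"))
    registerModule("always_terminate",
                   function(params, ws, seed) list(action = "terminate"))
  if (!moduleExists("always_fail"))
    registerModule("always_fail",
                   function(params, ws, seed) stop("bad parameter"))
  if (!moduleExists("skip_forward"))
    registerModule("skip_forward", function(params, ws, seed)
      list(action = "skip_to", label = params$label))

  # terminate marks the remainder skipped
  wf <- workflow(
    moduleSpec("noop_producer", wfParam("output_image", "output-image", "A")),
    moduleSpec("always_terminate"),
    moduleSpec("noop_transform",
               wfParam("input_image1", "input-image", "A"),
               wfParam("output_image", "output-image", "B")))
  out <- executeWorkflow(wf, newWorkspace())
  expect_equal(out@status, "terminated")
  expect_equal(out@moduleStatus, c("executed", "executed", "skipped"))

  # failure aborts with a recorded cause
  wf2 <- workflow(
    moduleSpec("always_fail"),
    moduleSpec("noop_producer", wfParam("output_image", "output-image", "A")))
  out2 <- executeWorkflow(wf2, newWorkspace())
  expect_equal(out2@status, "failed")
  expect_equal(out2@moduleStatus, c("failed", "skipped"))
  expect_match(out2@log, "bad parameter")

  # skip_to jumps over intermediate modules only
  wf3 <- workflow(
    moduleSpec("skip_forward", wfParam("label", "text", "Last")),
    moduleSpec("noop_producer", wfParam("output_image", "output-image", "A"),
               nickname = "Middle"),
    moduleSpec("noop_producer", wfParam("output_image", "output-image", "B"),
               nickname = "Last"))
  out3 <- executeWorkflow(wf3, newWorkspace())
  expect_equal(out3@status, "completed")
  expect_equal(out3@moduleStatus, c("executed", "skipped", "executed"))

  # every module is covered exactly once by a status
  expect_length(out3@moduleStatus, 3)
})

test_that("disabled modules are reported as such and never run", {
  registerNoopModules()
  wf <- chainWorkflow(c(TRUE, FALSE, TRUE))
  out <- executeWorkflow(wf, newWorkspace())
  expect_equal(out@moduleStatus, c("executed", "disabled", "disabled"))
  expect_equal(out@status, "completed")
})
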