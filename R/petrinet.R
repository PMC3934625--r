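# Canonical transition ids per configuration choice; the weight/column
# order (rigid, affine, RSGD, EO, linear, NN, bspline) groups the
# alternatives stage by stage.
weightedTransitionIds <- function() {
  c("t_rigid", "t_affine", "t_rsgd", "t_evo", "t_linear", "t_nn",
    "t_bspline")
}

configTransitions <- function(config) {
  c(switch(config@transformKind, rigid = "t_rigid", affine = "t_affine"),
    switch(config@optimizer, RSGD = "t_rsgd", EO = "t_evo"),
    switch(config@interpolator, linear = "t_linear", NN = "t_nn",
           bspline = "t_bspline"))
}

transitionsToConfig <- function(ids) {
  pick <- function(choices) {
    hit <- names(choices)[names(choices) %in% ids]
    if (length(hit) != 1L)
      stop("path must select exactly one transition per stage",
           call. = FALSE)
    choices[[hit]]
  }
  pipelineConfig(
    transformKind = pick(c(t_rigid = "rigid", t_affine = "affine")),
    optimizer = pick(c(t_rsgd = "RSGD", t_evo = "EO")),
    interpolator = pick(c(t_linear = "linear", t_nn = "NN",
                          t_bspline = "bspline")))
}

#' Build the registration workflow Petri net
#'
#' Places model the sequential processing states (data-in, then one state
#' after each decision: metric, transform, optimizer, interpolator, done),
#' transitions model the method choices of each functional block, and a
#' distinguished inaccuracy-counter place receives an arc from every
#' weighted transition so the token game can accumulate each fired
#' choice's inaccuracy contribution. The metric stage offers only mutual
#' information — the one similarity suited to multimodal intrasubject
#' registration — so its transition is unweighted: with no alternative its
#' impact is not separable from the rest of the chain. That leaves 7
#' weighted transitions (2 transforms + 2 optimizers + 3 interpolators)
#' and 2 x 2 x 3 = 12 end-to-end paths.
#'
#' @return an uncalibrated [PetriNetModel-class] (weights all \code{NA}).
#' @export
buildRegistrationNet <- function() {
  transitions <- data.frame(
    id = c("t_mi", weightedTransitionIds()),
    label = c("MI", "Rigid", "Affine", "RSGD", "1+1 EO", "Linear", "NN",
              "B-Spline"),
    stage = c("metric", "transform", "transform", "optimizer", "optimizer",
              "interpolator", "interpolator", "interpolator"),
    weighted = c(FALSE, rep(TRUE, 7)),
    stringsAsFactors = FALSE)
  places <- c("p_in", "p_metric", "p_transform", "p_optimizer",
              "p_interpolator", "p_done", "p_inaccuracy")
  stagePlace <- c(metric = "p_metric", transform = "p_transform",
                  optimizer = "p_optimizer", interpolator = "p_interpolator")
  prevPlace <- c(metric = "p_in", transform = "p_metric",
                 optimizer = "p_transform", interpolator = "p_optimizer")
  arcs <- do.call(rbind, lapply(seq_len(nrow(transitions)), function(i) {
    st <- transitions$stage[i]; id <- transitions$id[i]
    out <- rbind(data.frame(from = prevPlace[[st]], to = id,
                            cardinality = 1L),
                 data.frame(from = id, to = stagePlace[[st]],
                            cardinality = 1L))
    if (transitions$weighted[i])
      out <- rbind(out, data.frame(from = id, to = "p_inaccuracy",
                                   cardinality = 1L))
    out
  }))
  # interpolator stage completes the chain
  arcs$to[arcs$to == "p_interpolator"] <- "p_done"
  weights <- rep(NA_real_, 7)
  names(weights) <- weightedTransitionIds()
  new("PetriNetModel", places = places, counter = "p_inaccuracy",
      transitions = transitions, arcs = arcs, weights = weights)
}

#' @rdname PetriNetModel-class
#' @export
setMethod("netWeights", "PetriNetModel", function(object) object@weights)

#' @rdname PetriNetModel-class
#' @export
setMethod("netWeights<-", "PetriNetModel", function(object, value) {
  stopifnot(setequal(names(value), names(object@weights)))
  object@weights <- value[names(object@weights)]
  validObject(object)
  object
})

#' @rdname PetriNetModel-class
#' @export
setMethod("transitionTable", "PetriNetModel",
          function(object) object@transitions)

setMethod("show", "PetriNetModel", function(object) {
  tr <- object@transitions
  cat(sprintf("PetriNetModel: %d places, %d transitions (%d weighted)\n",
              length(object@places), nrow(tr), sum(tr$weighted)))
  cat(sprintf("  inaccuracy counter: %s\n", object@counter))
  if (all(is.na(object@weights))) {
    cat("  weights: not calibrated\n")
  } else {
    cat("  weights (mm):\n")
    w <- data.frame(transition = names(object@weights),
                    weight_mm = round(unname(object@weights), 4))
    print(w, row.names = FALSE)
  }
})

#' @rdname PetriPath-class
#' @export
setMethod("pathConfig", "PetriPath", function(object) object@config)

#' @rdname PetriPath-class
#' @export
setMethod("pathTransitions", "PetriPath",
          function(object) object@transitions)

setMethod("show", "PetriPath", function(object) {
  cat("PetriPath:", paste(object@transitions, collapse = " -> "), "\n")
})

#' Enumerate all source-to-sink paths of a stage-structured net
#'
#' Every path fires the metric transition followed by exactly one
#' transition per decision stage, in the same documented order as
#' [enumerateConfigs()] (transform outer, optimizer middle, interpolator
#' inner), so paths and configurations are in bijection.
#'
#' @param net a [PetriNetModel-class] as built by
#'   [buildRegistrationNet()].
#' @return list of [PetriPath-class] objects (12 for the registration
#'   net).
#' @export
enumeratePaths <- function(net) {
  tr <- net@transitions
  for (st in c("metric", "transform", "optimizer", "interpolator"))
    if (!any(tr$stage == st))
      stop("malformed net: missing stage ", st, call. = FALSE)
  lapply(enumerateConfigs(), function(cfg) {
    ids <- configTransitions(cfg)
    if (!all(ids %in% tr$id))
      stop("malformed net: missing transitions ",
           paste(setdiff(ids, tr$id), collapse = ", "), call. = FALSE)
    new("PetriPath", transitions = c("t_mi", ids), config = cfg)
  })
}

#' Play the token game along a path
#'
#' Fires the path's transitions in order under classical token semantics —
#' each firing consumes tokens from the transition's input places and
#' produces tokens at its output places per arc cardinality — while the
#' inaccuracy counter accumulates the (mm-valued, possibly negative)
#' weight of every fired weighted transition. If \code{abortThreshold} is
#' set and the running total exceeds it, firing stops early: the process
#' can be abandoned as soon as the predicted accuracy becomes
#' unacceptable.
#'
#' @param net a calibrated [PetriNetModel-class].
#' @param path a [PetriPath-class] from [enumeratePaths()].
#' @param abortThreshold mm, or \code{NULL} for no early stop.
#' @return list with \code{total} (mm in the counter), \code{aborted},
#'   \code{fired} (transition ids actually fired), and \code{marking}
#'   (final token counts per place).
#' @export
playTokenGame <- function(net, path, abortThreshold = NULL) {
  w <- net@weights
  needed <- intersect(path@transitions, names(w))
  if (any(is.na(w[needed])))
    stop("net is not calibrated: weights are missing", call. = FALSE)
  marking <- setNames(integer(length(net@places)), net@places)
  marking["p_in"] <- 1L
  total <- 0
  fired <- character(0)
  aborted <- FALSE
  for (id in path@transitions) {
    inputs <- net@arcs[net@arcs$to == id, , drop = FALSE]
    if (any(marking[inputs$from] < inputs$cardinality))
      stop("transition ", id, " is not enabled", call. = FALSE)
    marking[inputs$from] <- marking[inputs$from] - inputs$cardinality
    outputs <- net@arcs[net@arcs$from == id, , drop = FALSE]
    nonCounter <- outputs[outputs$to != net@counter, , drop = FALSE]
    marking[nonCounter$to] <- marking[nonCounter$to] + nonCounter$cardinality
    fired <- c(fired, id)
    if (id %in% names(w)) total <- total + w[[id]]
    if (!is.null(abortThreshold) && total > abortThreshold) {
      aborted <- TRUE
      break
    }
  }
  list(total = total, aborted = aborted, fired = fired, marking = marking)
}

#' Predict the inaccuracy of a configuration
#'
#' The a-priori predicted registration error of a pipeline configuration:
#' the sum of the calibrated weights of the three stage transitions its
#' path selects, in mm. Equals the counter total of a full token game
#' along that path.
#'
#' @param net a calibrated [PetriNetModel-class].
#' @param config a [PipelineConfig-class].
#' @return predicted MGE in mm.
#' @export
predictInaccuracy <- function(net, config) {
  w <- net@weights
  ids <- configTransitions(config)
  if (any(is.na(w[ids])))
    stop("net is not calibrated: weights are missing", call. = FALSE)
  sum(w[ids])
}

#' Serialize a Petri net to JSON
#'
#' @param net a [PetriNetModel-class].
#' @param path file path to write; the JSON document holds places,
#'   counter, transitions (with stage tags), arcs and weights, enough to
#'   reload a calibrated net for prediction-only runs.
#' @return \code{path}, invisibly.
#' @export
writePetriNet <- function(net, path) {
  w <- as.list(net@weights)
  w[vapply(w, is.na, logical(1))] <- list(NULL)   # uncalibrated -> null
  doc <- list(places = net@places, counter = net@counter,
              transitions = net@transitions, arcs = net@arcs,
              weights = w)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Petri net from JSON
#'
#' @param path file written by [writePetriNet()].
#' @return a [PetriNetModel-class].
#' @export
readPetriNet <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  wt <- doc$transitions$id[doc$transitions$weighted]
  w <- vapply(wt, function(id) {
    x <- doc$weights[[id]]
    if (is.null(x) || length(x) == 0 || !is.numeric(x)) NA_real_
    else as.numeric(x)
  }, numeric(1))
  names(w) <- wt
  new("PetriNetModel", places = doc$places, counter = doc$counter,
      transitions = as.data.frame(doc$transitions),
      arcs = as.data.frame(doc$arcs), weights = w)
}
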