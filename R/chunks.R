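#' Declare a memory chunk
#'
#' A chunk is a bundle of feature/value pairs held in declarative memory;
#' retrieval cues are matched against these features. Feature values are
#' stored as character strings.
#'
#' @param id chunk label, unique within a condition.
#' @param features named list or vector of feature values (non-empty).
#' @param creation_time optional elapsed time since the chunk was encoded
#'   (seconds, > 0); drives base-level decay when supplied.
#' @return An object of class `chunk`.
#' @examples
#' chunk("subject", c(number = "pl", person = "3"))
#' @export
chunk <- function(id, features, creation_time = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("`id` must be a single non-empty string", call. = FALSE)
  }
  features <- as.list(features)
  if (length(features) == 0L || is.null(names(features)) ||
      any(!nzchar(names(features)))) {
    stop("`features` must be a non-empty named list", call. = FALSE)
  }
  features <- lapply(features, as.character)
  if (!is.null(creation_time)) {
    if (!is.numeric(creation_time) || length(creation_time) != 1L ||
        !is.finite(creation_time) || creation_time <= 0) {
      stop("invalid schedule: `creation_time` must be a positive number ",
           "of seconds", call. = FALSE)
    }
  }
  structure(list(id = id, features = features,
                 creation_time = creation_time),
            class = "chunk")
}

#' Declare a retrieval cue set
#'
#' Cues are feature specifications posted at a retrieval site. Each cue
#' carries a source-activation weight (defaulting to an equal share of a
#' total source activation of 1) and a fan count: the number of chunks in
#' memory associated with the cue's required value, which dilutes the
#' associative strength `MAS - log(fan)` spread to matching chunks.
#'
#' @param cues named character vector/list of required values, one per cue.
#' @param weights optional named numeric vector of source-activation
#'   weights; defaults to `1/length(cues)` each.
#' @param fan optional named integer vector of fan counts (all >= 1);
#'   usually left `NULL` and filled in per condition by
#'   [condition_spec()].
#' @return An object of class `cue_set`.
#' @examples
#' cue_set(c(number = "sg", person = "3"))
#' @export
cue_set <- function(cues, weights = NULL, fan = NULL) {
  cues <- as.list(cues)
  if (length(cues) == 0L || is.null(names(cues)) ||
      any(!nzchar(names(cues)))) {
    stop("`cues` must be a non-empty named list of required values",
         call. = FALSE)
  }
  cues <- lapply(cues, as.character)
  nms <- names(cues)
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(cues), length(cues)), nms)
  } else {
    weights <- unlist(weights)
    if (!all(nms %in% names(weights))) {
      stop("`weights` must name every cue", call. = FALSE)
    }
    weights <- weights[nms]
    if (any(!is.finite(weights)) || any(weights < 0) || sum(weights) <= 0) {
      stop("`weights` must be non-negative with a positive sum",
           call. = FALSE)
    }
  }
  if (!is.null(fan)) {
    fan <- unlist(fan)
    if (!all(nms %in% names(fan))) {
      stop("invalid spec: `fan` must name every cue", call. = FALSE)
    }
    fan <- fan[nms]
    if (any(!is.finite(fan)) || any(fan < 1)) {
      stop("invalid spec: fan counts must be >= 1", call. = FALSE)
    }
  }
  structure(list(cues = cues, weights = weights, fan = fan),
            class = "cue_set")
}

#' Specify a retrieval condition
#'
#' Bundles candidate chunks with the retrieval cues they compete for. When
#' a cue's fan count is not given it defaults to the number of chunks in
#' the condition carrying the cue's required value (at least 1).
#'
#' @param chunks list of [chunk()] objects (non-empty, unique ids).
#' @param cues a [cue_set()], or a named vector of required values to be
#'   promoted to one.
#' @param name optional condition label.
#' @return An object of class `condition_spec`.
#' @examples
#' cond <- condition_spec(
#'   chunks = list(chunk("target", c(number = "pl", person = "3")),
#'                 chunk("distractor", c(number = "sg", person = "3"))),
#'   cues = c(number = "sg", person = "3")
#' )
#' cond$cues$fan
#' @export
condition_spec <- function(chunks, cues, name = NULL) {
  if (!is.list(chunks) || length(chunks) == 0L) {
    stop("invalid spec: a condition needs at least one chunk",
         call. = FALSE)
  }
  if (!all(vapply(chunks, inherits, logical(1), "chunk"))) {
    stop("`chunks` must be a list of chunk() objects", call. = FALSE)
  }
  ids <- vapply(chunks, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("invalid spec: chunk ids must be unique within a condition",
         call. = FALSE)
  }
  if (!inherits(cues, "cue_set")) cues <- cue_set(cues)
  if (is.null(cues$fan)) {
    fan <- vapply(names(cues$cues), function(j) {
      carriers <- vapply(chunks, function(ch) {
        identical(ch$features[[j]], cues$cues[[j]])
      }, logical(1))
      max(1L, sum(carriers))
    }, integer(1))
    cues$fan <- fan
  }
  structure(list(chunks = chunks, cues = cues, name = name,
                 ids = ids),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("Retrieval condition", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", length(x$chunks), "chunk(s):", paste(x$ids, collapse = ", "),
      "\n")
  cat("Cues:",
      paste(names(x$cues$cues), unlist(x$cues$cues),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
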