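#' Multi-image analysis session
#'
#' A session holds several images side by side, each with its calibration
#' and whatever analysis results have been produced for it, so that work
#' on one image is never lost when switching to another. Entries are
#' keyed by a user-chosen image id; retrieving an entry returns exactly
#' the state last stored for it.
#'
#' @return `new_session()` returns an empty session object.
#' @examples
#' s <- new_session()
#' session_put(s, "img1", image = matrix(255, 4, 4), calibration = calibration(1))
#' session_set_result(s, "img1", "note", "checked")
#' session_get_result(s, "img1", "note")
#' @export
new_session <- function() {
  structure(list(entries = new.env(parent = emptyenv()),
                 order = new.env(parent = emptyenv())),
            class = "adiposize_session")
}

#' @rdname new_session
#' @param session A session from [new_session()].
#' @param id Character image id, unique within the session.
#' @param image Image array (see [image-conventions]).
#' @param calibration Optional [calibration()].
#' @export
session_put <- function(session, id, image, calibration = NULL) {
  stopifnot(inherits(session, "adiposize_session"), is.character(id))
  if (!exists(id, envir = session$entries, inherits = FALSE)) {
    n <- length(ls(session$order))
    assign(id, n + 1L, envir = session$order)
  }
  assign(id, list(image = image, calibration = calibration,
                  results = list()),
         envir = session$entries)
  invisible(session)
}

#' @rdname new_session
#' @export
session_get <- function(session, id) {
  if (!exists(id, envir = session$entries, inherits = FALSE))
    stop_domain(paste0("no session entry with id: ", id))
  get(id, envir = session$entries, inherits = FALSE)
}

#' @rdname new_session
#' @export
session_ids <- function(session) {
  ids <- ls(session$order)
  ids[order(unlist(mget(ids, envir = session$order), use.names = FALSE))]
}

#' @rdname new_session
#' @param name Result slot name, e.g. `"population"` or `"histogram"`.
#' @param value Any R object to save for this image.
#' @export
session_set_result <- function(session, id, name, value) {
  entry <- session_get(session, id)
  entry$results[[name]] <- value
  assign(id, entry, envir = session$entries)
  invisible(session)
}

#' @rdname new_session
#' @export
session_get_result <- function(session, id, name) {
  session_get(session, id)$results[[name]]
}
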