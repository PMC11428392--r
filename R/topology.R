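# Landmark graph construction, IO and validation.

#' Default 37-landmark hand topology
#'
#' The shipped convention for a 37-landmark hand: a chained wrist/carpal block
#' (landmarks 1-13, containing the two wrist landmarks 2 and 6 that define the
#' physical scale), five finger chains running from each metacarpophalangeal
#' joint to its fingertip (the thumb chain has four landmarks, the others
#' five), attachments of the metacarpal row to the carpal chain, and rung
#' edges between corresponding joints of adjacent fingers that strengthen the
#' spatial constraint. The global set contains the two wrist landmarks, the
#' five metacarpophalangeal joints and the five fingertips. The graph is a
#' convention, not an anatomical ground truth; datasets with different
#' numbering can supply their own edge list via [readTopology()].
#'
#' @return a [Topology-class] with 37 vertices.
#' @export
defaultHandTopology <- function() {
  chain <- function(v) cbind(v[-length(v)], v[-1])
  edges <- rbind(
    chain(1:13),                                # wrist/carpal chain
    cbind(9:13, c(18L, 17L, 16L, 15L, 14L)),    # metacarpal attachments
    chain(c(14, 22, 23, 24, 25)),               # finger chains (MCP -> tip)
    chain(c(15, 26, 27, 28, 29)),
    chain(c(16, 30, 31, 32, 33)),
    chain(c(17, 34, 35, 36, 37)),
    chain(c(18, 19, 20, 21)),                   # thumb (four landmarks)
    chain(14:18),                               # rungs: MCP row
    chain(c(22, 26, 30, 34, 19)),               # rungs: proximal joint row
    chain(c(23, 27, 31, 35, 20)),               # rungs: middle joint row
    chain(c(24, 28, 32, 36)),
    chain(c(25, 29, 33, 37, 21))                # rungs: fingertips
  )
  Topology(37L, edges,
           globalSet = c(2L, 6L, 14L, 15L, 16L, 17L, 18L,
                         21L, 25L, 29L, 33L, 37L))
}

#' Finger grouping of the default hand configuration
#'
#' Five ordered chains (metacarpophalangeal joint to fingertip) covering the
#' 24 occludable finger-joint landmarks; the thumb has four.
#' @return list of integer vectors.
#' @export
fingerGrouping <- function() {
  list(thumb = c(18L, 19L, 20L, 21L),
       finger2 = c(14L, 22L, 23L, 24L, 25L),
       finger3 = c(15L, 26L, 27L, 28L, 29L),
       finger4 = c(16L, 30L, 31L, 32L, 33L),
       finger5 = c(17L, 34L, 35L, 36L, 37L))
}

#' Validate a topology
#'
#' @param topology a [Topology-class].
#' @return list with `connected` (logical), `components` (membership vector),
#'   `ok` (overall flag) and `messages` (diagnostics).
#' @export
validateTopology <- function(topology) {
  n <- topology@nLandmarks
  comp <- seq_len(n)
  find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
  for (k in seq_len(nrow(topology@edges))) {
    ra <- find(topology@edges[k, 1]); rb <- find(topology@edges[k, 2])
    if (ra != rb) comp[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  connected <- length(unique(roots)) == 1
  msgs <- character()
  if (!connected)
    msgs <- c(msgs, sprintf("graph has %d connected components", length(unique(roots))))
  iso <- setdiff(seq_len(n), unique(c(topology@edges)))
  if (length(iso)) msgs <- c(msgs, paste("isolated landmarks:", paste(iso, collapse = ",")))
  list(connected = connected, components = match(roots, unique(roots)),
       ok = connected, messages = msgs)
}

#' Read / write a topology as a plain-text edge list
#'
#' Format: one `"i j"` pair per line (1-based landmark indices); an optional
#' line `"global: i j k ..."` lists the global landmark set; an optional line
#' `"n: <count>"` fixes the vertex count (otherwise the maximum index is
#' used). `#` starts a comment.
#'
#' @param path file path.
#' @param nLandmarks vertex count override.
#' @return `readTopology` returns a [Topology-class].
#' @export
readTopology <- function(path, nLandmarks = NULL) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  globals <- integer(); nDecl <- NULL
  edges <- list()
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (startsWith(ln, "global:")) {
      globals <- as.integer(strsplit(trimws(sub("^global:", "", ln)), "[[:space:]]+")[[1]])
    } else if (startsWith(ln, "n:")) {
      nDecl <- as.integer(trimws(sub("^n:", "", ln)))
    } else {
      parts <- suppressWarnings(as.integer(strsplit(ln, "[[:space:]]+")[[1]]))
      if (length(parts) != 2 || any(is.na(parts)))
        stop(sprintf("malformed topology line %d: '%s'", k, ln))
      edges[[length(edges) + 1]] <- parts
    }
  }
  edges <- do.call(rbind, edges)
  n <- if (!is.null(nLandmarks)) nLandmarks else if (!is.null(nDecl)) nDecl
       else max(edges, globals)
  if (any(edges < 1) || any(edges > n))
    stop("edge index out of range for ", n, " landmarks")
  t <- Topology(n, edges, globals)
  validObject(t)
  t
}

#' @rdname readTopology
#' @param topology a [Topology-class] to write.
#' @export
writeTopology <- function(topology, path) {
  lines <- c(paste("n:", topology@nLandmarks),
             if (length(topology@globalSet))
               paste("global:", paste(topology@globalSet, collapse = " ")),
             apply(topology@edges, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a topology to / from a JSON representation
#'
#' @param topology a [Topology-class].
#' @param path JSON file path.
#' @export
writeTopologyJSON <- function(topology, path) {
  jsonlite::write_json(list(n_landmarks = topology@nLandmarks,
                            edges = topology@edges,
                            global_set = topology@globalSet),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTopologyJSON
#' @export
readTopologyJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  Topology(x$n_landmarks, x$edges, x$global_set)
}
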