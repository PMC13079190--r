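#' Canonical 17-keypoint joint names
#'
#' Returns the fixed joint dictionary (COCO ordering) used throughout the
#' package: nose, eyes, ears, shoulders, elbows, wrists, hips, knees, ankles.
#'
#' @return Character vector of length 17.
#' @export
joint_names <- function() COCO17

# left/right partner of every joint (self for midline joints)
.mirror_map <- function() {
  m <- COCO17
  swap <- function(a, b) {
    m[match(a, COCO17)] <<- b
    m[match(b, COCO17)] <<- a
  }
  for (part in c("eye", "ear", "shoulder", "elbow", "wrist", "hip",
                 "knee", "ankle")) {
    swap(paste0("left_", part), paste0("right_", part))
  }
  m
}

# base undirected limb/torso edge list (16 edges, standard COCO skeleton)
.base_edges <- function() {
  rbind(
    c("nose", "left_eye"), c("nose", "right_eye"),
    c("left_eye", "left_ear"), c("right_eye", "right_ear"),
    c("left_shoulder", "right_shoulder"),
    c("left_shoulder", "left_elbow"), c("left_elbow", "left_wrist"),
    c("right_shoulder", "right_elbow"), c("right_elbow", "right_wrist"),
    c("left_shoulder", "left_hip"), c("right_shoulder", "right_hip"),
    c("left_hip", "right_hip"),
    c("left_hip", "left_knee"), c("left_knee", "left_ankle"),
    c("right_hip", "right_knee"), c("right_knee", "right_ankle")
  )
}

.canon_edge <- function(a, b) {
  i <- match(a, COCO17); j <- match(b, COCO17)
  if (anyNA(c(i, j))) stop("unknown joint name: ", a, " / ", b, call. = FALSE)
  if (i == j) stop("self-edges are not allowed in the skeleton graph",
                   call. = FALSE)
  paste(COCO17[min(i, j)], COCO17[max(i, j)], sep = "|")
}

#' Build the sport-weighted 17-keypoint skeleton graph
#'
#' Constructs the COCO-17 skeleton augmented for the unilateral loading
#' pattern of racquet strokes: the racket-arm chain (dominant-side
#' shoulder-elbow, elbow-wrist and the shoulder's torso attachment) is
#' up-weighted by `arm_weight`, and two explicit cross-lateral edges
#' (racket shoulder to opposite hip, racket-side hip to opposite shoulder)
#' are added at `cross_weight`.  All other edges keep the baseline weight 1,
#' so the multipliers are literal edge values.
#'
#' @param handedness `"left"` or `"right"`: the racket-holding side.
#' @param arm_weight Multiplier for the racket-arm chain (default 1.5).
#' @param cross_weight Multiplier for the cross-lateral edges (default 1.3).
#' @return An object of class `skeleton_graph`: a list with `nodes` (the 17
#'   joint names in canonical order), `edges` (m x 2 character matrix),
#'   `weights` (numeric vector, one per edge) and `handedness`.
#' @examples
#' g <- build_skeleton_graph("right")
#' A <- normalized_adjacency(g)
#' @export
build_skeleton_graph <- function(handedness = c("right", "left"),
                                 arm_weight = 1.5, cross_weight = 1.3) {
  handedness <- match.arg(handedness)
  dom <- handedness
  opp <- if (dom == "right") "left" else "right"
  edges <- .base_edges()
  keys <- apply(edges, 1, function(e) .canon_edge(e[1], e[2]))
  w <- rep(1, nrow(edges))

  chain <- c(
    .canon_edge(paste0(dom, "_shoulder"), paste0(dom, "_elbow")),
    .canon_edge(paste0(dom, "_elbow"), paste0(dom, "_wrist")),
    .canon_edge(paste0(dom, "_shoulder"), paste0(dom, "_hip"))
  )
  w[keys %in% chain] <- arm_weight

  cross <- rbind(
    c(paste0(dom, "_shoulder"), paste0(opp, "_hip")),
    c(paste0(dom, "_hip"), paste0(opp, "_shoulder"))
  )
  edges <- rbind(edges, cross)
  w <- c(w, cross_weight, cross_weight)
  keys <- c(keys, apply(cross, 1, function(e) .canon_edge(e[1], e[2])))
  if (anyDuplicated(keys)) stop("duplicate edges in skeleton graph")

  structure(
    list(nodes = COCO17, edges = edges, weights = w, handedness = handedness),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("Sport-weighted skeleton graph (", length(x$nodes), " joints, ",
      nrow(x$edges), " edges, ", x$handedness, "-handed)\n", sep = "")
  tab <- table(x$weights)
  for (wv in names(tab)) {
    cat(sprintf("  weight %-4s: %d edges\n", wv, tab[[wv]]))
  }
  invisible(x)
}

# dense weighted adjacency (no self-connections)
.adjacency_matrix <- function(graph) {
  A <- matrix(0, 17, 17, dimnames = list(COCO17, COCO17))
  for (k in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges[k, 1], COCO17)
    j <- match(graph$edges[k, 2], COCO17)
    A[i, j] <- A[j, i] <- graph$weights[k]
  }
  A
}

#' Symmetrically normalized adjacency with self-connections
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)`, the propagation matrix of the
#' skeleton graph convolution, where `A` is the weighted adjacency, the
#' identity adds self-connections and `D` is the row-sum degree diagonal of
#' `A + I`.  Self-connections are added here and never stored in the graph.
#'
#' @param graph A `skeleton_graph` (or any list with `edges`/`weights`).
#' @return Symmetric non-negative 17 x 17 matrix.
#' @export
normalized_adjacency <- function(graph) {
  A <- .adjacency_matrix(graph) + diag(17)
  d <- rowSums(A)
  Dm <- 1 / sqrt(d)
  An <- A * (Dm %o% Dm)
  (An + t(An)) / 2  # kill round-off asymmetry
}

#' Mirror a keypoint sequence about the vertical midline
#'
#' Reflects horizontal coordinates (about `x = 0` in world coordinates, or
#' about the frame's vertical midline in image coordinates) and swaps the
#' left/right joint labels, so the result is the same motion performed by the
#' mirror-image athlete.  Applying it twice is the identity.
#'
#' @param seq A `keypoint_sequence`.
#' @param midline Reflection axis for image coordinates; defaults to the mean
#'   horizontal coordinate so world sequences centered off-origin mirror in
#'   place.  Ignored (taken as 0) for `world3d` sequences.
#' @return The mirrored `keypoint_sequence`.
#' @export
mirror_keypoints <- function(seq, midline = NULL) {
  stopifnot(inherits(seq, "keypoint_sequence"))
  co <- seq$coords
  if (seq$mode == "world3d") {
    co[, , 1] <- -co[, , 1]
  } else {
    if (is.null(midline)) midline <- mean(range(co[, , 1]))
    co[, , 1] <- 2 * midline - co[, , 1]
  }
  perm <- match(.mirror_map(), COCO17)
  co <- co[, perm, , drop = FALSE]
  conf <- seq$conf[, perm, drop = FALSE]
  out <- seq
  out$coords <- co
  out$conf <- conf
  out
}

#' Export a skeleton graph to JSON
#'
#' Writes node order, edge list and per-edge weights as a small JSON document
#' so alternative topologies can be plugged in.
#'
#' @param graph A `skeleton_graph`.
#' @param path Output file path.
#' @export
write_skeleton_json <- function(graph, path) {
  doc <- list(
    schema = "ttasym-skeleton/1",
    handedness = graph$handedness,
    nodes = graph$nodes,
    edges = apply(graph$edges, 1, function(e) list(e[1], e[2])),
    weights = graph$weights
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a skeleton graph from JSON
#'
#' @param path Path written by [write_skeleton_json()].
#' @return A `skeleton_graph`.
#' @export
read_skeleton_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(doc$nodes) != 17L) {
    stop("skeleton JSON must define exactly 17 nodes", call. = FALSE)
  }
  edges <- doc$edges
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) unlist(e)))
  }
  edges <- matrix(as.character(edges), ncol = 2)
  structure(
    list(nodes = unlist(doc$nodes), edges = edges,
         weights = as.numeric(doc$weights),
         handedness = doc$handedness),
    class = "skeleton_graph"
  )
}
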