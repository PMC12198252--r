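#' Bifurcating pulmonary-artery tree
#'
#' A `pa_tree` represents the main pulmonary artery (MPA), its bifurcation
#' into the right and left pulmonary arteries (RPA/LPA), and the outlet
#' branches on each side. Segments are straight cylinders: each has an id, a
#' parent id (`NA` for the MPA root), a side label, a radius and a length
#' (cm); cross-sectional area is `pi * r^2`.
#'
#' @param segments `data.frame` with columns `id`, `parent`, `label`, `side`,
#'   `radius`, `length`.
#' @return Object of class `pa_tree`.
#' @export
pa_tree <- function(segments) {
  req <- c("id", "parent", "label", "side", "radius", "length")
  if (!all(req %in% names(segments))) {
    stop("`segments` must have columns ", paste(req, collapse = ", "))
  }
  segments$area <- pi * segments$radius^2
  tr <- structure(list(segments = segments), class = "pa_tree")
  validate_pa_tree(tr)
  tr
}

validate_pa_tree <- function(tree) {
  seg <- tree$segments
  if (any(seg$radius <= 0) || any(seg$length <= 0)) {
    stop("all segment radii and lengths must be strictly positive")
  }
  if (any(abs(seg$area - pi * seg$radius^2) > 1e-12 * seg$area)) {
    stop("segment areas inconsistent with radii")
  }
  root <- seg$id[is.na(seg$parent)]
  if (length(root) != 1L) stop("tree must have exactly one root (MPA)")
  kids_of_root <- seg$id[!is.na(seg$parent) & seg$parent == root]
  if (length(kids_of_root) != 2L) {
    stop("the MPA must have exactly two principal children (RPA, LPA)")
  }
  sides <- seg$side[match(kids_of_root, seg$id)]
  if (!setequal(sides, c("RPA", "LPA"))) {
    stop("principal children must be labelled RPA and LPA")
  }
  r_root <- seg$radius[seg$id == root]
  if (any(seg$radius[match(kids_of_root, seg$id)] > r_root)) {
    stop("MPA radius must be >= each principal-branch radius")
  }
  has_child <- seg$id %in% seg$parent
  non_outlet <- seg$id[has_child]
  # every non-outlet segment has >= 1 child by construction of has_child;
  # check reachability instead: every segment's parent must exist
  par <- seg$parent[!is.na(seg$parent)]
  if (!all(par %in% seg$id)) stop("dangling parent references in tree")
  invisible(tree)
}

#' @export
print.pa_tree <- function(x, ...) {
  seg <- x$segments
  out <- outlet_ids(x)
  cat(sprintf(
    "Pulmonary-artery tree: %d segments, MPA radius %.3f cm, %d RPA / %d LPA outlets\n",
    nrow(seg), mpa_radius(x),
    sum(seg$side[match(out, seg$id)] == "RPA"),
    sum(seg$side[match(out, seg$id)] == "LPA")))
  invisible(x)
}

# --- accessors ---------------------------------------------------------------

root_id <- function(tree) tree$segments$id[is.na(tree$segments$parent)]

#' Tree accessors
#'
#' `mpa_radius()` returns the root (MPA) radius in cm; `outlet_ids()` the ids
#' of all leaf segments, optionally restricted to one side;
#' `principal_id()` the id of the RPA or LPA principal branch;
#' `outlet_areas()` the leaf cap areas in cm^2.
#'
#' @param tree A [pa_tree()].
#' @param side `"RPA"` or `"LPA"` (optional for `outlet_ids`).
#' @name tree_accessors
#' @export
mpa_radius <- function(tree) tree$segments$radius[is.na(tree$segments$parent)]

#' @rdname tree_accessors
#' @export
outlet_ids <- function(tree, side = NULL) {
  seg <- tree$segments
  ids <- seg$id[!(seg$id %in% seg$parent)]
  if (!is.null(side)) ids <- ids[seg$side[match(ids, seg$id)] == side]
  ids
}

#' @rdname tree_accessors
#' @export
principal_id <- function(tree, side) {
  seg <- tree$segments
  rid <- root_id(tree)
  kid <- seg$id[!is.na(seg$parent) & seg$parent == rid & seg$side == side]
  if (length(kid) != 1L) stop("no principal branch on side ", side)
  kid
}

#' @rdname tree_accessors
#' @export
outlet_areas <- function(tree, side = NULL) {
  ids <- outlet_ids(tree, side)
  tree$segments$area[match(ids, tree$segments$id)]
}

# ordered vector of segment ids on the path from root to `id` (inclusive)
path_to_root <- function(tree, id) {
  seg <- tree$segments
  p <- integer(0)
  cur <- id
  while (!is.na(cur)) {
    p <- c(cur, p)
    cur <- seg$parent[match(cur, seg$id)]
  }
  p
}

# --- generator ---------------------------------------------------------------

#' Generate a synthetic pulmonary-artery tree
#'
#' Emulates the reconstructed PA anatomy used for patient-specific outflow
#' modelling: one MPA segment, an RPA and an LPA principal branch, and
#' `n_outlets_per_side` outlet branches per side (the clinical models
#' reconstruct roughly ten per lung). Outlet radii are log-normally dispersed
#' around a common base value and then rescaled so the summed outlet area per
#' side equals `outlet_area_ratio` times the principal-branch area (default
#' 1.5, emulating the widening of the peripheral vascular bed and keeping
#' outlet velocities physiological).
#'
#' Principal-branch radii follow a Murray-type taper,
#' `r_principal = mpa_radius * 2^(-1/2.3)`, so the MPA radius always bounds
#' the principal radii. The construction is fully deterministic given `seed`.
#'
#' @param n_outlets_per_side Number of outlet branches per lung (>= 1).
#' @param mpa_radius MPA radius, cm.
#' @param radius_dispersion Log-normal sigma of outlet radii
#'   (0 = identical outlets).
#' @param seed Integer seed; the generator is deterministic given
#'   (parameters, seed).
#' @param outlet_area_ratio Summed outlet area per side relative to the
#'   principal-branch area.
#' @return A [pa_tree()].
#' @examples
#' tr <- generate_pa_tree(10, mpa_radius = 1.3, radius_dispersion = 0.3, seed = 1)
#' length(outlet_ids(tr))  # 20
#' @export
generate_pa_tree <- function(n_outlets_per_side = 10L, mpa_radius = 1.3,
                             radius_dispersion = 0.3, seed = 0L,
                             outlet_area_ratio = 1.5) {
  if (n_outlets_per_side < 1L) stop("`n_outlets_per_side` must be >= 1")
  if (mpa_radius <= 0) stop("`mpa_radius` must be positive")
  if (radius_dispersion < 0) stop("`radius_dispersion` must be >= 0")
  n <- as.integer(n_outlets_per_side)
  r_mpa <- mpa_radius
  r_pr <- r_mpa * 2^(-1 / 2.3)      # Murray-type taper at the bifurcation
  a_pr <- pi * r_pr^2

  seg <- data.frame(
    id = 1:3, parent = c(NA, 1L, 1L),
    label = c("MPA", "RPA", "LPA"), side = c("MPA", "RPA", "LPA"),
    radius = c(r_mpa, r_pr, r_pr),
    length = c(2.5 * r_mpa, 4 * r_pr, 4 * r_pr),
    stringsAsFactors = FALSE
  )

  withr_seed <- function(expr) {  # local RNG scope, restores global state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
  }
  radii <- withr_seed({
    lapply(c("RPA", "LPA"), function(s) {
      z <- stats::rnorm(n)
      r0 <- sqrt(outlet_area_ratio * a_pr / (n * pi))
      r <- r0 * exp(radius_dispersion * z)
      # rescale so summed outlet area per side is exact
      r * sqrt(outlet_area_ratio * a_pr / sum(pi * r^2))
    })
  })
  if (n == 1L) return(pa_tree(seg))   # principals are the outlets
  nid <- 3L
  for (k in 1:2) {
    s <- c("RPA", "LPA")[k]
    r <- radii[[k]]
    seg <- rbind(seg, data.frame(
      id = nid + seq_len(n), parent = principal_stub(k),
      label = paste0(s, "_outlet_", seq_len(n)), side = s,
      radius = r, length = 8 * r, stringsAsFactors = FALSE
    ))
    nid <- nid + n
  }
  pa_tree(seg)
}

# parent id of outlet branches on side k (1 = RPA principal id 2, 2 = LPA id 3)
principal_stub <- function(k) c(2L, 3L)[k]

# --- measurement sites -------------------------------------------------------

#' Locate the index-measurement cross-section in a branch
#'
#' Branch indices are evaluated at a cross-section whose centerline distance
#' from the PA bifurcation equals the MPA radius. The site is found by walking
#' distally from the principal branch; if the remaining arclength exceeds a
#' segment, the walk descends into that segment's largest-radius child. For
#' the MPA (the study protocol defines branch sites only) the site is placed
#' at the MPA mid-length cross-section.
#'
#' @param tree A [pa_tree()].
#' @param branch `"MPA"`, `"RPA"` or `"LPA"`.
#' @return Object of class `measurement_site`: fields `branch`, `segment_id`,
#'   `arclength` (cm into the segment), `radius`, `area`.
#' @export
measurement_site <- function(tree, branch = c("RPA", "LPA", "MPA")) {
  branch <- match.arg(branch)
  seg <- tree$segments
  if (branch == "MPA") {
    rid <- root_id(tree)
    return(new_site("MPA", rid, seg$length[match(rid, seg$id)] / 2,
                    seg$radius[match(rid, seg$id)]))
  }
  target <- mpa_radius(tree)
  cur <- principal_id(tree, branch)
  remaining <- target
  repeat {
    len <- seg$length[match(cur, seg$id)]
    if (remaining <= len) {
      return(new_site(branch, cur, remaining, seg$radius[match(cur, seg$id)]))
    }
    remaining <- remaining - len
    kids <- seg$id[!is.na(seg$parent) & seg$parent == cur]
    if (length(kids) == 0L) {
      stop(sprintf(
        "MPA radius (%.3f cm) exceeds the total centerline length of the %s branch",
        target, branch))
    }
    cur <- kids[which.max(seg$radius[match(kids, seg$id)])]
  }
}

new_site <- function(branch, segment_id, arclength, radius) {
  structure(list(branch = branch, segment_id = segment_id,
                 arclength = arclength, radius = radius,
                 area = pi * radius^2),
            class = "measurement_site")
}

#' @export
print.measurement_site <- function(x, ...) {
  cat(sprintf("%s measurement site: segment %d, %.3f cm into segment, r = %.3f cm\n",
              x$branch, x$segment_id, x$arclength, x$radius))
  invisible(x)
}

# --- serialization -----------------------------------------------------------

#' Serialize a PA tree to/from JSON
#'
#' Segments are written as a flat list with parent references under an
#' explicit schema version, so trees can be stored alongside boundary
#' conditions and reloaded exactly.
#'
#' @param tree A [pa_tree()].
#' @param path File path.
#' @return `read_tree_json()` returns a [pa_tree()]; `write_tree_json()`
#'   returns `path` invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(schema = "pahemo-pa-tree/1", segments = tree$segments)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || obj$schema != "pahemo-pa-tree/1") {
    stop("unrecognized tree JSON schema")
  }
  seg <- obj$segments
  seg$parent <- as.integer(seg$parent)
  pa_tree(seg[, c("id", "parent", "label", "side", "radius", "length")])
}
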