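#' Wrap angles into (-180, 180]
#'
#' All angular arithmetic in the package operates on wrapped deviations;
#' headings and targets are stored in degrees in the screen frame,
#' counterclockwise positive.
#'
#' @param a numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
#' @examples
#' wrap_deg(c(270, -180, 45))
wrap_deg <- function(a) 180 - ((180 - a) %% 360)

#' Angular position of a target relative to the frequent target
#'
#' Returns the signed wrapped difference `target - frequent` and the absolute
#' probe distance collapsed onto the session classes 0/30/60/90 degrees.
#' Targets must lie in the session set (frequent + 0, +/-30, +/-60, +/-90)
#' unless `snap` is allowed, in which case angles within `snap_tol` of a class
#' are collapsed onto it (used for jittered frequent-location trials).
#'
#' @param target_deg numeric vector, target angles (degrees, screen frame).
#' @param frequent_deg scalar or vector, the frequent-target angle.
#' @param snap logical, collapse near-miss angles onto the nearest class.
#' @param snap_tol tolerance in degrees used when `snap = TRUE`.
#' @return list with components `rel` (signed degrees) and `distance`
#'   (absolute class in {0, 30, 60, 90}).
#' @export
probe_distance_of <- function(target_deg, frequent_deg, snap = FALSE,
                              snap_tol = 15) {
  rel <- wrap_deg(target_deg - frequent_deg)
  d <- abs(rel)
  classes <- c(0, 30, 60, 90)
  nearest <- classes[pmax(1L, apply(abs(outer(d, classes, "-")), 1L, which.min))]
  off <- abs(d - nearest)
  tol <- if (snap) snap_tol else 1e-6
  if (any(off > tol)) {
    bad <- target_deg[which(off > tol)[1L]]
    stop("target not in session set: ", format(bad),
         " relative to frequent target ", format(frequent_deg[1L]))
  }
  list(rel = rel, distance = nearest)
}

#' Session target set for a given frequent-target location
#'
#' Seven locations at 0, +/-30, +/-60 and +/-90 degrees relative to the
#' frequent target, wrapped to [0, 360). For a frequent target at 60 degrees
#' this is the canonical set 0, 30, 60, 90, 120, 150, 330.
#'
#' @param frequent_deg scalar frequent-target angle in degrees.
#' @return sorted numeric vector of seven target angles in [0, 360).
#' @export
session_targets <- function(frequent_deg) {
  stopifnot(length(frequent_deg) == 1L, is.finite(frequent_deg))
  sort((frequent_deg + c(-90, -60, -30, 0, 30, 60, 90)) %% 360)
}
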