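# Electrode geometry for the extended 10-20 (10-10) system.
#
# Positions are constructed on a unit sphere from the system's own percentage
# rules rather than copied from any digitised cap: the outer 10% ring holds 20
# electrodes spaced 18 degrees apart at 72 degrees inclination from the vertex,
# midline electrodes sit on the nasion-inion arc at 18-degree steps, and
# interior electrodes divide the great-circle arc from the ring electrode of
# their row to the midline electrode into equal parts (spherical
# interpolation). This reproduces published 10-20 geometry (18 degrees between
# adjacent midline electrodes, mirror symmetry across the midline).

# Spherical linear interpolation between two unit vectors.
slerp <- function(u, v, frac) {
  omega <- acos(max(-1, min(1, sum(u * v))))
  if (omega < 1e-12) return(u)
  (sin((1 - frac) * omega) * u + sin(frac * omega) * v) / sin(omega)
}

sph_unit <- function(incl_deg, az_deg) {
  i <- incl_deg * pi / 180
  a <- az_deg * pi / 180
  c(sin(i) * cos(a), sin(i) * sin(a), cos(i))
}

# Full coordinate table for the labels this package recognises.
# Azimuth convention: 0 = nasion (front), positive = left hemisphere.
ten_ten_table <- local({
  ring_lab <- c("Fpz", "Fp2", "AF8", "F8", "FT8", "T8", "TP8", "P8", "PO8",
                "O2", "Oz", "O1", "PO7", "P7", "TP7", "T7", "FT7", "F7",
                "AF7", "Fp1")
  ring_az <- c(0, -18, -36, -54, -72, -90, -108, -126, -144, -162,
               180, 162, 144, 126, 108, 90, 72, 54, 36, 18)
  pos <- list()
  for (k in seq_along(ring_lab)) pos[[ring_lab[k]]] <- sph_unit(72, ring_az[k])
  mid <- list(AFz = c(54, 0), Fz = c(36, 0), FCz = c(18, 0), Cz = c(0, 0),
              CPz = c(18, 180), Pz = c(36, 180), POz = c(54, 180))
  for (lab in names(mid)) pos[[lab]] <- sph_unit(mid[[lab]][1], mid[[lab]][2])
  # interior rows: arcs from the ring electrode to the midline electrode
  rows <- list(
    list(left = "F7",  right = "F8",  mid = "Fz",
         lab_l = c("F5", "F3", "F1"),    lab_r = c("F6", "F4", "F2")),
    list(left = "FT7", right = "FT8", mid = "FCz",
         lab_l = c("FC5", "FC3", "FC1"), lab_r = c("FC6", "FC4", "FC2")),
    list(left = "T7",  right = "T8",  mid = "Cz",
         lab_l = c("C5", "C3", "C1"),    lab_r = c("C6", "C4", "C2")),
    list(left = "TP7", right = "TP8", mid = "CPz",
         lab_l = c("CP5", "CP3", "CP1"), lab_r = c("CP6", "CP4", "CP2")),
    list(left = "P7",  right = "P8",  mid = "Pz",
         lab_l = c("P5", "P3", "P1"),    lab_r = c("P6", "P4", "P2")),
    list(left = "AF7", right = "AF8", mid = "AFz",
         lab_l = "AF3", lab_r = "AF4"),
    list(left = "PO7", right = "PO8", mid = "POz",
         lab_l = "PO3", lab_r = "PO4")
  )
  for (r in rows) {
    nl <- length(r$lab_l)
    fr <- seq_len(nl) / (nl + 1)
    for (k in seq_len(nl)) {
      pos[[r$lab_l[k]]] <- slerp(pos[[r$left]],  pos[[r$mid]], fr[k])
      pos[[r$lab_r[k]]] <- slerp(pos[[r$right]], pos[[r$mid]], fr[k])
    }
  }
  m <- do.call(rbind, pos)
  rownames(m) <- names(pos)
  m
})

#' Default 58-channel cap and 56-channel analysis set
#'
#' `cap58_labels()` returns the 58 scalp labels of the default recording cap
#' (extended 10-20 grid without `Fpz`, `AF7`, `AF8`). `analysis_labels()`
#' returns the default analysis set: the same cap minus `P5` and `P6`,
#' leaving 56 channels.
#'
#' @return Character vector of 10-10 channel labels.
#' @export
cap58_labels <- function() {
  setdiff(rownames(ten_ten_table), c("Fpz", "AF7", "AF8"))
}

#' @rdname cap58_labels
#' @export
analysis_labels <- function() setdiff(cap58_labels(), c("P5", "P6"))

#' Construct a montage with standard 10-20/10-10 positions
#'
#' Builds electrode positions on a unit sphere from the 10-20 system's
#' percentage rules, together with a 2D azimuthal-equidistant projection
#' (right = positive x, anterior = positive y). Deterministic for a given
#' label list.
#'
#' @param labels Character vector of recognised 10-20/10-10 channel names.
#' @return An object of class `eeg_montage`: list with `labels`, `pos3d`
#'   (n x 3 unit vectors), `pos2d` (n x 2), and `neighbor_map` (`NULL` until
#'   [build_neighbors()] is called).
#' @seealso [build_neighbors()]
#' @export
standard_montage <- function(labels) {
  if (length(labels) == 0) stopf("empty label list")
  unknown <- setdiff(labels, rownames(ten_ten_table))
  if (length(unknown) > 0)
    stopf("unknown channel label(s): %s", paste(unknown, collapse = ", "))
  p3 <- ten_ten_table[labels, , drop = FALSE]
  incl <- acos(pmin(1, pmax(-1, p3[, 3]))) / pi * 2  # 0 at vertex, 1 at equator
  az <- atan2(p3[, 2], p3[, 1])
  p2 <- cbind(x = -incl * sin(az), y = incl * cos(az))
  rownames(p2) <- labels
  structure(list(labels = labels, pos3d = p3, pos2d = p2,
                 neighbor_map = NULL),
            class = "eeg_montage")
}

#' Populate a montage's neighbor graph
#'
#' Two electrodes are neighbors when their great-circle angular distance is
#' at most `max_angle` degrees. The relation is symmetric and irreflexive.
#' At the default 25 degrees the 56-channel analysis set gets 4-8 neighbors
#' per channel, the usual sensor-adjacency density.
#'
#' @param montage An `eeg_montage`.
#' @param max_angle Maximum angular distance in degrees (> 0).
#' @return The montage with `neighbor_map` set: a named list, label ->
#'   character vector of neighboring labels. Channels left without any
#'   neighbor trigger a warning.
#' @export
build_neighbors <- function(montage, max_angle = 25) {
  stopifnot(inherits(montage, "eeg_montage"), max_angle > 0)
  ang <- angular_distance(montage$pos3d, montage$pos3d)
  diag(ang) <- Inf
  nb <- lapply(seq_along(montage$labels), function(i)
    montage$labels[ang[i, ] <= max_angle])
  names(nb) <- montage$labels
  isolated <- names(nb)[vapply(nb, length, 1L) == 0L]
  if (length(isolated) > 0)
    warnf("isolated channel(s) at max_angle=%g: %s", max_angle,
          paste(isolated, collapse = ", "))
  montage$neighbor_map <- nb
  montage$max_angle <- max_angle
  montage
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels%s\n", length(x$labels),
              if (is.null(x$neighbor_map)) "" else
                sprintf(", neighbor graph at %g deg", x$max_angle)))
  invisible(x)
}

#' Export a montage to JSON
#'
#' @param montage An `eeg_montage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage_json <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  obj <- list(labels = montage$labels,
              pos3d = unname(apply(montage$pos3d, 1, as.numeric,
                                   simplify = FALSE)),
              pos2d = unname(apply(montage$pos2d, 1, as.numeric,
                                   simplify = FALSE)),
              neighbor_map = montage$neighbor_map)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
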