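#' Idealized 32-channel 10-20 montage on the unit sphere
#'
#' Builds the electrode montage used throughout the package: 32 scalp
#' channels of the international 10-20/10-10 system placed on an ideal unit
#' sphere by the standard geometric construction (midline and circumferential
#' arcs divided in 10%/20% steps, intermediate rows by spherical
#' interpolation). Positions drive the surface-Laplacian kernel and the
#' topographic exports; they are idealized, not digitized, coordinates.
#'
#' The coordinate frame is right-handed with +x toward the right ear,
#' +y toward the nasion, and +z toward the vertex.
#'
#' @param a_priori Label of the a-priori channel of interest (default
#'   `"Oz"`, over primary visual cortex).
#' @return An object of class `ssvep_montage`: a list with `labels`
#'   (character, length 32), `pos` (32 x 3 matrix of unit vectors, rownames =
#'   labels) and `a_priori`.
#' @examples
#' mon <- montage_1020()
#' mon$labels
#' @export
montage_1020 <- function(a_priori = "Oz") {
  sph <- function(incl, az) {
    i <- incl * pi / 180
    a <- az * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  slerp <- function(p, q, t) {
    om <- acos(max(-1, min(1, sum(p * q))))
    v <- (sin((1 - t) * om) * p + sin(t * om) * q) / sin(om)
    v / sqrt(sum(v^2))
  }
  nlz <- function(...) {
    v <- colMeans(do.call(rbind, list(...)))
    v / sqrt(sum(v^2))
  }
  mirror <- function(p) c(-p[1], p[2], p[3])

  pos <- list(
    Cz  = sph(0, 0),
    Fz  = sph(36, 0),   Pz = sph(36, 180),
    Oz  = sph(72, 180),
    Fp1 = sph(72, -18), Fp2 = sph(72, 18),
    F7  = sph(72, -54), F8  = sph(72, 54),
    T7  = sph(72, -90), T8  = sph(72, 90),
    P7  = sph(72, -126), P8 = sph(72, 126),
    O1  = sph(72, -162), O2 = sph(72, 162),
    C3  = sph(36, -90), C4  = sph(36, 90)
  )
  pos$F3  <- slerp(pos$F7, pos$Fz, 0.5); pos$F4 <- mirror(pos$F3)
  pos$P3  <- slerp(pos$P7, pos$Pz, 0.5); pos$P4 <- mirror(pos$P3)
  pos$FC5 <- nlz(pos$F7, pos$F3, pos$T7, pos$C3); pos$FC6 <- mirror(pos$FC5)
  pos$FC1 <- nlz(pos$F3, pos$Fz, pos$C3, pos$Cz); pos$FC2 <- mirror(pos$FC1)
  pos$CP5 <- nlz(pos$T7, pos$C3, pos$P7, pos$P3); pos$CP6 <- mirror(pos$CP5)
  pos$CP1 <- nlz(pos$C3, pos$Cz, pos$P3, pos$Pz); pos$CP2 <- mirror(pos$CP1)
  pos$PO7 <- slerp(pos$P7, pos$O1, 0.5); pos$PO8 <- mirror(pos$PO7)
  pos$PO3 <- nlz(pos$P3, pos$O1);        pos$PO4 <- mirror(pos$PO3)

  labels <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO3", "PO4", "PO8",
    "O1", "Oz", "O2"
  )
  m <- do.call(rbind, pos[labels])
  rownames(m) <- labels
  colnames(m) <- c("x", "y", "z")
  stopifnot(!anyDuplicated(labels), a_priori %in% labels)
  structure(
    list(labels = labels, pos = m, a_priori = a_priori),
    class = "ssvep_montage"
  )
}

#' @export
print.ssvep_montage <- function(x, ...) {
  cat("<ssvep_montage> ", length(x$labels), " channels; a priori: ",
      x$a_priori, "\n", sep = "")
  invisible(x)
}

# Mastoid reference positions (below the 10-20 ring, not part of the scalp
# montage). Used by the synthetic-data generator so that mastoid channels
# carry a physically plausible share of the planted signal.
mastoid_positions <- function() {
  sph <- function(incl, az) {
    i <- incl * pi / 180
    a <- az * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  m <- rbind(M1 = sph(115, -105), M2 = sph(115, 105))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Angular distance between montage positions and a reference channel
#'
#' @param pos n x 3 matrix of unit-sphere positions.
#' @param ref Unit vector (length 3) of the reference position.
#' @return Angles in radians.
#' @keywords internal
angular_distance <- function(pos, ref) {
  acos(pmax(-1, pmin(1, drop(pos %*% ref))))
}
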