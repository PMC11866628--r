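#' The 19-channel 10-20 scalp montage
#'
#' Channel labels, schematic 2D head coordinates and a neighbor map for the
#' 19 electrodes of the international 10-20 system (Fp1 ... O2). Coordinates
#' use a unit-radius head disk (x toward the right ear, y toward the nasion);
#' the outer ring of electrodes lies on the circle, the mid ring at half
#' radius. Two channels are neighbors when their Euclidean distance,
#' normalized by the head diameter, is below `cutoff`.
#'
#' @param cutoff neighbor cutoff as a fraction of the head diameter.
#'   The default 0.35 links each electrode to its immediately adjacent
#'   positions only.
#' @return an object of class `eeg_montage`: a list with `labels` (ordered
#'   channel names), `coords` (19 x 2 matrix), and `neighbors` (named list of
#'   character vectors; the relation is symmetric and every channel has at
#'   least one neighbor).
#' @examples
#' m <- montage_1020()
#' m$neighbors$Cz
#' @export
montage_1020 <- function(cutoff = 0.35) {
  stopifnot(is.numeric(cutoff), cutoff > 0, cutoff < 1)
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4",
              "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  deg <- function(d) d * pi / 180
  circ <- function(a) c(cos(deg(a)), sin(deg(a)))
  coords <- rbind(
    Fp1 = circ(108), Fp2 = circ(72),
    F7 = circ(144), F3 = (circ(144) + c(0, 0.5)) / 2,
    Fz = c(0, 0.5),
    F4 = (circ(36) + c(0, 0.5)) / 2, F8 = circ(36),
    T3 = circ(180), C3 = c(-0.5, 0), Cz = c(0, 0),
    C4 = c(0.5, 0), T4 = circ(0),
    T5 = circ(216), P3 = (circ(216) + c(0, -0.5)) / 2,
    Pz = c(0, -0.5),
    P4 = (circ(-36) + c(0, -0.5)) / 2, T6 = circ(-36),
    O1 = circ(-108), O2 = circ(-72)
  )[labels, , drop = FALSE]
  colnames(coords) <- c("x", "y")
  d <- as.matrix(stats::dist(coords)) / 2  # normalize by head diameter
  neighbors <- lapply(labels, function(ch) {
    labels[d[ch, ] < cutoff & labels != ch]
  })
  names(neighbors) <- labels
  structure(list(labels = labels, coords = coords, neighbors = neighbors),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " channels: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}
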