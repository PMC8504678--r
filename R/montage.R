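#' Idealized 10-20 / 10-10 electrode positions on the unit sphere
#'
#' Returns the built-in idealized spherical coordinate table used by
#' [build_montage()]. The head is a unit sphere; positions follow the classic
#' 10-20 construction:
#'
#' * the outer 10% ring (FPz, FP1/2, F7/8, FT7/8, T7/8, TP7/8, P7/8, O1/2, Oz)
#'   lies at 92 degrees inclination from the vertex (the conventional
#'   just-below-equator placement of spherical head models);
#' * the midline F/C/P row (Fz, C3/4, Pz) lies at 45 degrees, the FC/CP row
#'   (FCz, CPz) at 22.5 degrees, Cz at the vertex;
#' * intermediate electrodes (F3/4, P3/4, FC3/4, CP3/4, AFz, ...) are
#'   unit-sphere arc midpoints of their row neighbours, e.g. F3 is midway
#'   between Fz and F7, FC3 midway between F3 and C3.
#'
#' Legacy names T3/T4/T5/T6 are aliases of T7/T8/P7/P8. M1/M2 are idealized
#' mastoid positions below the ring, used only when the simulator carries
#' reference channels.
#'
#' @return A tibble with columns `label`, `theta` (inclination from the
#'   vertex, degrees), `phi` (azimuth from the anterior midline, degrees,
#'   positive towards the right ear), and unit-sphere Cartesian `x` (right),
#'   `y` (anterior), `z` (superior).
#' @examples
#' electrode_positions()
#' @export
electrode_positions <- function() {
  deg <- pi / 180
  arc_mid <- function(a, b) {
    m <- a + b
    m / sqrt(sum(m^2))
  }
  xyz <- function(theta, phi) {
    c(sin(theta * deg) * sin(phi * deg),
      sin(theta * deg) * cos(phi * deg),
      cos(theta * deg))
  }
  pos <- list(
    Cz  = xyz(0, 0),
    FCz = xyz(22.5, 0),   CPz = xyz(22.5, 180),
    Fz  = xyz(45, 0),     Pz  = xyz(45, 180),
    C3  = xyz(45, -90),   C4  = xyz(45, 90),
    FPz = xyz(92, 0),     Oz  = xyz(92, 180)
  )
  ring <- c(FP1 = -18, FP2 = 18, F7 = -54, F8 = 54, FT7 = -72, FT8 = 72,
            T7 = -90, T8 = 90, TP7 = -108, TP8 = 108, P7 = -126, P8 = 126,
            O1 = -162, O2 = 162)
  for (nm in names(ring)) pos[[nm]] <- xyz(92, ring[[nm]])
  pos$F3  <- arc_mid(pos$Fz, pos$F7);   pos$F4  <- arc_mid(pos$Fz, pos$F8)
  pos$P3  <- arc_mid(pos$Pz, pos$P7);   pos$P4  <- arc_mid(pos$Pz, pos$P8)
  pos$FC3 <- arc_mid(pos$F3, pos$C3);   pos$FC4 <- arc_mid(pos$F4, pos$C4)
  pos$CP3 <- arc_mid(pos$P3, pos$C3);   pos$CP4 <- arc_mid(pos$P4, pos$C4)
  pos$AFz <- arc_mid(pos$FPz, pos$Fz)
  pos$M1  <- xyz(120, -100);            pos$M2  <- xyz(120, 100)
  P <- do.call(rbind, pos)
  out <- tibble(
    label = rownames(P),
    x = unname(P[, 1]), y = unname(P[, 2]), z = unname(P[, 3])
  )
  out$theta <- acos(pmin(1, pmax(-1, out$z))) / deg
  out$phi <- ifelse(abs(out$x) + abs(out$y) < 1e-12, 0,
                    atan2(out$x, out$y) / deg)
  out[, c("label", "theta", "phi", "x", "y", "z")]
}

# legacy 10-20 names resolved to 10-10 positions
.legacy_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Default scalp channel set
#'
#' The 31 recording channels of the modified 10-20 cap this package was built
#' around: 7 midline sites (FPz, Fz, FCz, Cz, CPz, Pz, Oz) and 12 lateral
#' pairs. AFz serves as ground and is not a data channel.
#'
#' @param legacy_names Use T3/T4/T5/T6 instead of T7/T8/P7/P8 (default `TRUE`,
#'   matching older cap labelling).
#' @return Character vector of 31 channel labels.
#' @export
default_channels <- function(legacy_names = TRUE) {
  lateral10 <- c("T7", "T8", "P7", "P8")
  if (legacy_names) lateral10 <- c("T3", "T4", "T5", "T6")
  c("FPz", "Fz", "FCz", "Cz", "CPz", "Pz", "Oz",
    "FP1", "FP2", "F3", "F4", "F7", "F8", "FT7", "FT8",
    "FC3", "FC4", "C3", "C4", "TP7", "TP8", "CP3", "CP4",
    lateral10[1:2], "P3", "P4", lateral10[3:4], "O1", "O2")
}

#' Build a spherical-head montage
#'
#' Places the requested channels at the built-in idealized 10-20 coordinates
#' ([electrode_positions()]), scaled to a spherical head of the given
#' circumference.
#'
#' @param channels Character vector of 10-20 / 10-10 labels. Legacy names
#'   T3/T4/T5/T6 are accepted. Defaults to the 31-channel set of
#'   [default_channels()].
#' @param circumference_cm Head circumference in cm (default 56); the sphere
#'   radius is `circumference_cm / (2 * pi)`.
#' @return An object of class `ow_montage`: a tibble with columns `label`,
#'   `theta`, `phi` (degrees) and `x`, `y`, `z` (cm, scaled to the head
#'   radius), with attributes `radius_cm` and `circumference_cm`.
#' @examples
#' m <- build_montage()
#' attr(m, "radius_cm") # 56 / (2 * pi) = 8.913 cm
#' @export
build_montage <- function(channels = default_channels(), circumference_cm = 56) {
  stopifnot_scalar_number(circumference_cm, "circumference_cm", min = 1e-6)
  if (anyDuplicated(channels)) {
    abort("duplicate channel labels in `channels`")
  }
  tab <- electrode_positions()
  resolved <- ifelse(channels %in% names(.legacy_aliases),
                     .legacy_aliases[channels], channels)
  bad <- setdiff(resolved, tab$label)
  if (length(bad) > 0) {
    abort(sprintf("unknown electrode label(s): %s", paste(bad, collapse = ", ")))
  }
  radius <- circumference_cm / (2 * pi)
  m <- tab[match(resolved, tab$label), ]
  m$label <- channels
  m$x <- m$x * radius
  m$y <- m$y * radius
  m$z <- m$z * radius
  structure(as_tibble(m),
            radius_cm = radius,
            circumference_cm = circumference_cm,
            class = c("ow_montage", class(tibble())))
}

montage_xyz <- function(montage) {
  P <- as.matrix(montage[, c("x", "y", "z")])
  rownames(P) <- montage$label
  P
}

# Pairwise electrode distance matrix in cm. Chord = straight-line 3D distance;
# geodesic = arc length along the scalp sphere.
electrode_distances <- function(montage, metric = c("chord", "geodesic")) {
  metric <- match.arg(metric)
  P <- montage_xyz(montage)
  D <- as.matrix(stats::dist(P))
  if (metric == "geodesic") {
    r <- attr(montage, "radius_cm")
    D <- 2 * r * asin(pmin(D / (2 * r), 1))
  }
  D
}

#' Build the spatial adjacency graph of a montage
#'
#' Links every electrode pair whose inter-electrode distance does not exceed
#' `threshold_cm`. The default metric is the 3D chord distance between scalp
#' positions; `metric = "geodesic"` uses arc length along the sphere.
#'
#' @param montage An `ow_montage` from [build_montage()].
#' @param threshold_cm Linking distance in cm (default 6.02, the neighbourhood
#'   radius used for cluster formation on a 56 cm head).
#' @param metric `"chord"` (default) or `"geodesic"`.
#' @return An object of class `ow_adjacency`: a named list of neighbour label
#'   sets (one entry per montage channel), with attributes `threshold_cm`,
#'   `metric`, and `labels`.
#' @examples
#' adj <- build_adjacency(build_montage())
#' mean(lengths(adj)) # about 3.1 neighbours per electrode
#' @export
build_adjacency <- function(montage, threshold_cm = 6.02,
                            metric = c("chord", "geodesic")) {
  metric <- match.arg(metric)
  if (nrow(montage) == 0) abort("montage is empty")
  stopifnot_scalar_number(threshold_cm, "threshold_cm", min = 0)
  D <- electrode_distances(montage, metric)
  labs <- montage$label
  nb <- lapply(seq_along(labs), function(i) {
    labs[which(D[i, ] <= threshold_cm & seq_along(labs) != i)]
  })
  names(nb) <- labs
  structure(nb,
            threshold_cm = threshold_cm, metric = metric, labels = labs,
            class = "ow_adjacency")
}

#' Summarise an adjacency graph
#'
#' @param adjacency An `ow_adjacency` from [build_adjacency()].
#' @return A one-row tibble with `n_channels`, `n_edges`, `mean_degree`,
#'   `sd_degree`, `threshold_cm`.
#' @export
adjacency_summary <- function(adjacency) {
  deg <- lengths(adjacency)
  tibble(
    n_channels = length(deg),
    n_edges = sum(deg) / 2,
    mean_degree = mean(deg),
    sd_degree = sd(deg),
    threshold_cm = attr(adjacency, "threshold_cm")
  )
}

#' Adjacency graph as an edge list
#'
#' @inheritParams adjacency_summary
#' @return Tibble with columns `a`, `b` (each undirected edge once,
#'   `a` before `b` in montage order).
#' @export
adjacency_edges <- function(adjacency) {
  labs <- attr(adjacency, "labels")
  idx <- setNames(seq_along(labs), labs)
  rows <- purrr::imap(unclass(adjacency), function(nbrs, lab) {
    keep <- nbrs[idx[nbrs] > idx[[lab]]]
    if (length(keep) == 0) return(NULL)
    tibble(a = lab, b = keep)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) tibble(a = character(), b = character()) else out
}

# adjacency as a 0/1 matrix in montage channel order
adjacency_matrix <- function(adjacency) {
  labs <- attr(adjacency, "labels")
  A <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (lab in labs) A[lab, adjacency[[lab]]] <- 1
  A
}

#' Read and write montage / adjacency text formats
#'
#' `write_montage()` and `read_montage()` exchange a montage as plain TSV with
#' columns `label`, `theta`, `phi` (degrees; head circumference stored in a
#' comment line). `write_montage_besa()` writes BESA-style spherical text
#' (`label theta phi`, tab-separated, no header). `write_adjacency()` dumps an
#' edge-list TSV.
#'
#' @param montage,adjacency Objects from [build_montage()] /
#'   [build_adjacency()].
#' @param path File path.
#' @return `read_montage()` returns an `ow_montage`; the writers return the
#'   path invisibly.
#' @name montage_io
NULL

#' @rdname montage_io
#' @export
write_montage <- function(montage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# circumference_cm: %.10g", attr(montage, "circumference_cm")), con)
  write.table(montage[, c("label", "theta", "phi")], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname montage_io
#' @export
read_montage <- function(path) {
  first <- readLines(path, n = 1)
  circ <- 56
  if (grepl("^# circumference_cm:", first)) {
    circ <- as.numeric(sub("^# circumference_cm:\\s*", "", first))
  }
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  deg <- pi / 180
  radius <- circ / (2 * pi)
  m <- tibble(
    label = tab$label, theta = tab$theta, phi = tab$phi,
    x = radius * sin(tab$theta * deg) * sin(tab$phi * deg),
    y = radius * sin(tab$theta * deg) * cos(tab$phi * deg),
    z = radius * cos(tab$theta * deg)
  )
  structure(m, radius_cm = radius, circumference_cm = circ,
            class = c("ow_montage", class(tibble())))
}

#' @rdname montage_io
#' @export
write_montage_besa <- function(montage, path) {
  write.table(montage[, c("label", "theta", "phi")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname montage_io
#' @export
write_adjacency <- function(adjacency, path) {
  write.table(adjacency_edges(adjacency), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
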