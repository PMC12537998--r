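# Sensor geometry: standard montages on the unit sphere, adjacency graphs,
# and the spherical-spline machinery shared by channel interpolation and the
# surface-Laplacian CSD transform.

# Idealized angular table for a 32-channel 10-20 cap (FCz reference, Fpz
# ground). Columns: polar angle theta (signed, negative = left hemisphere)
# and azimuth phi, both degrees; Cartesian position is
#   (sin(theta) cos(phi), sin(theta) sin(phi), cos(theta)),
# so +x is the right preauricular direction, +y the nasion, +z the vertex.
.std32_angles <- function() {
  tab <- matrix(c(
    -92, -72,   # Fp1
     92,  72,   # Fp2
    -92, -36,   # F7
    -60, -51,   # F3
     46,  90,   # Fz
     60,  51,   # F4
     92,  36,   # F8
    -71, -21,   # FC5
    -32, -45,   # FC1
     32,  45,   # FC2
     71,  21,   # FC6
    -92,   0,   # T7
    -46,   0,   # C3
      0,   0,   # Cz
     46,   0,   # C4
     92,   0,   # T8
   -113, -18,   # TP9
    -71,  21,   # CP5
    -32,  45,   # CP1
     32, -45,   # CP2
     71, -21,   # CP6
    113,  18,   # TP10
    -92,  36,   # P7
    -60,  51,   # P3
     46, -90,   # Pz
     60, -51,   # P4
     92, -36,   # P8
   -113,  54,   # PO9
    -92,  72,   # O1
     92, -90,   # Oz
     92, -72,   # O2
    113, -54    # PO10
  ), ncol = 2, byrow = TRUE)
  rownames(tab) <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5",
                     "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
                     "TP9", "CP5", "CP1", "CP2", "CP6", "TP10", "P7", "P3",
                     "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
  colnames(tab) <- c("theta", "phi")
  tab
}

#' Build a standard EEG montage
#'
#' Constructs unit-sphere electrode positions for a named standard layout.
#' Currently ships the 32-channel 10-20 arrangement used by common gel caps
#' (FCz reference, Fpz ground), with positions derived from the idealized
#' angular placement of the extended 10-20 system.
#'
#' @param layout Layout identifier; only `"std32"` is known.
#' @return An object of class `eeg_montage`: a list with `labels` (character),
#'   `positions` (channels x 3 matrix of unit vectors), `reference_label`,
#'   and `ground_label`.
#' @export
#' @examples
#' mon <- build_standard_montage("std32")
#' mon$labels
build_standard_montage <- function(layout = "std32") {
  if (!identical(layout, "std32")) {
    stop("unknown montage layout: ", layout)
  }
  ang <- .std32_angles() * pi / 180
  pos <- cbind(sin(ang[, 1]) * cos(ang[, 2]),
               sin(ang[, 1]) * sin(ang[, 2]),
               cos(ang[, 1]))
  rownames(pos) <- rownames(.std32_angles())
  colnames(pos) <- c("x", "y", "z")
  new_montage(labels = rownames(pos), positions = pos,
              reference_label = "FCz", ground_label = "Fpz")
}

#' Create a montage from labels and positions
#'
#' @param labels Character vector of unique channel names.
#' @param positions Numeric channels x 3 matrix; rows are normalized to unit
#'   length (they must be within 1e-6 of unit norm already, or `normalize`
#'   must be `TRUE`).
#' @param reference_label,ground_label Names of the (non-measurement)
#'   reference and ground electrodes.
#' @param normalize If `TRUE`, project positions onto the unit sphere.
#' @return An `eeg_montage` object.
#' @export
new_montage <- function(labels, positions, reference_label = "FCz",
                        ground_label = "Fpz", normalize = FALSE) {
  positions <- as.matrix(positions)
  if (length(labels) != nrow(positions) || ncol(positions) != 3) {
    stop("positions must be a length(labels) x 3 matrix")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (any(c(reference_label, ground_label) %in% labels)) {
    stop("reference/ground labels must not be measurement channels")
  }
  nrm <- sqrt(rowSums(positions^2))
  if (normalize) {
    if (any(nrm == 0)) stop("zero-length position cannot be normalized")
    positions <- positions / nrm
  } else if (any(abs(nrm - 1) > 1e-6)) {
    stop("positions must lie on the unit sphere (or pass normalize = TRUE)")
  }
  rownames(positions) <- labels
  structure(list(labels = as.character(labels), positions = positions,
                 reference_label = reference_label,
                 ground_label = ground_label),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels (ref %s, gnd %s)\n",
              length(x$labels), x$reference_label, x$ground_label))
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Pairwise great-circle angles between montage channels
#'
#' @param montage An `eeg_montage`.
#' @return Symmetric channels x channels matrix of angles in radians.
#' @export
channel_angles <- function(montage) {
  cs <- tcrossprod(montage$positions)
  acos(pmin(pmax(cs, -1), 1))
}

#' Sensor adjacency graph
#'
#' Defines which channels count as spatial neighbours for cluster formation.
#' The `distance` method links every pair whose great-circle angle is at most
#' `threshold`; the `delaunay` method triangulates the sensor cloud on the
#' sphere (convex-hull faces) and links triangle edges, discarding edges
#' longer than pi/2 that arise from the open underside of the cap.
#'
#' @param montage An `eeg_montage`.
#' @param method `"distance"` (default) or `"delaunay"`.
#' @param threshold Great-circle angle in radians for the distance method.
#'   The default 0.78 rad gives a median degree of 4-6 on the shipped
#'   32-channel layout.
#' @return An `adjacency_graph`: list with boolean `matrix`, `method`,
#'   `threshold`.
#' @export
compute_adjacency <- function(montage, method = c("distance", "delaunay"),
                              threshold = 0.78) {
  method <- match.arg(method)
  p <- length(montage$labels)
  if (p < 1) stop("montage must contain at least one channel")
  adj <- matrix(FALSE, p, p, dimnames = list(montage$labels, montage$labels))
  if (p >= 2) {
    ang <- channel_angles(montage)
    if (method == "distance") {
      if (!is.numeric(threshold) || threshold <= 0) {
        stop("distance threshold must be positive")
      }
      adj <- ang <= threshold
    } else {
      adj <- .delaunay_adjacency(montage$positions, ang)
    }
    diag(adj) <- FALSE
  }
  structure(list(matrix = adj, method = method,
                 threshold = if (method == "distance") threshold else NA_real_),
            class = "adjacency_graph")
}

# Convex-hull triangulation of points on the sphere by brute force: a triple
# is a hull face iff every other point lies on one side of its plane.
# Adequate for sensor-count-sized inputs.
.delaunay_adjacency <- function(pos, ang) {
  p <- nrow(pos)
  adj <- matrix(FALSE, p, p, dimnames = dimnames(ang))
  if (p < 3) {
    if (p == 2) adj[1, 2] <- adj[2, 1] <- TRUE
    return(adj)
  }
  eps <- 1e-9
  for (i in seq_len(p - 2)) {
    for (j in seq(i + 1, p - 1)) {
      for (k in seq(j + 1, p)) {
        n <- .cross3(pos[j, ] - pos[i, ], pos[k, ] - pos[i, ])
        d <- (pos %*% n) - sum(n * pos[i, ])
        d <- d[-c(i, j, k)]
        if (all(d <= eps) || all(d >= -eps)) {
          adj[i, j] <- adj[j, i] <- TRUE
          adj[i, k] <- adj[k, i] <- TRUE
          adj[j, k] <- adj[k, j] <- TRUE
        }
      }
    }
  }
  adj[ang > pi / 2] <- FALSE
  adj
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# --- spherical splines (Perrin-style) --------------------------------------

# Legendre polynomials P_1..P_n evaluated at x (vector), by the three-term
# recurrence; returns length(x) x n matrix.
.legendre_table <- function(x, n) {
  out <- matrix(0, length(x), n)
  pm2 <- rep(1, length(x))        # P_0
  pm1 <- x                        # P_1
  out[, 1] <- pm1
  if (n >= 2) {
    for (k in 2:n) {
      pk <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
      out[, k] <- pk
      pm2 <- pm1
      pm1 <- pk
    }
  }
  out
}

# g and h kernels of the spherical spline:
#   g(x) = (1/4pi) sum_n (2n+1) / (n(n+1))^m     P_n(x)
#   h(x) = (1/4pi) sum_n (2n+1) / (n(n+1))^(m-1) P_n(x)
# h is (minus) the Laplace-Beltrami image of g, since each P_n(x . x_i) is a
# degree-n surface harmonic in x. Series truncated at `nterms` terms with an
# absolute term tolerance.
.spline_gh <- function(x, m = 4, nterms = 50, tol = 1e-10) {
  x <- pmin(pmax(x, -1), 1)
  n <- seq_len(nterms)
  cg <- (2 * n + 1) / (n * (n + 1))^m
  ch <- (2 * n + 1) / (n * (n + 1))^(m - 1)
  keep <- max(which(cg > tol * cg[1] | ch > tol * ch[1]))
  n <- n[seq_len(keep)]
  P <- .legendre_table(as.vector(x), keep)
  g <- (P %*% cg[seq_len(keep)]) / (4 * pi)
  h <- (P %*% ch[seq_len(keep)]) / (4 * pi)
  dm <- if (is.matrix(x)) dim(x) else NULL
  list(g = if (is.null(dm)) as.vector(g) else matrix(g, dm[1], dm[2]),
       h = if (is.null(dm)) as.vector(h) else matrix(h, dm[1], dm[2]))
}

# Solve the constrained spline system on the good channels:
#   [G + lambda I, 1; 1', 0] [c; d] = [v; 0]
# Returns the (p+1) x p matrix mapping channel data v to (c, d).
.spline_solve_matrix <- function(pos_good, m, lambda, nterms = 50) {
  pg <- nrow(pos_good)
  cosang <- tcrossprod(pos_good)
  G <- .spline_gh(cosang, m = m, nterms = nterms)$g
  A <- rbind(cbind(G + diag(lambda, pg), rep(1, pg)),
             c(rep(1, pg), 0))
  solve(A)[, seq_len(pg), drop = FALSE]
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the rows of `data` belonging to `bad` channels with
#' Perrin-style spherical-spline estimates computed from the remaining good
#' channels; good rows are returned untouched.
#'
#' @param data Numeric channels x time matrix, rows ordered as
#'   `montage$labels`.
#' @param bad Character vector of bad channel labels (or integer indices).
#' @param montage An `eeg_montage` matching the rows of `data`.
#' @param m Spline stiffness (integer, default 4).
#' @param lambda Ridge regularization added to the spline system diagonal.
#' @param nterms Legendre series truncation.
#' @return Matrix of the same shape as `data`.
#' @export
spline_interpolate <- function(data, bad, montage, m = 4, lambda = 1e-5,
                               nterms = 50) {
  data <- as.matrix(data)
  p <- length(montage$labels)
  if (nrow(data) != p) stop("data rows must match montage channels")
  if (is.character(bad)) {
    if (!all(bad %in% montage$labels)) stop("bad channels not in montage")
    bad <- match(bad, montage$labels)
  }
  bad <- unique(as.integer(bad))
  if (length(bad) == 0) return(data)
  good <- setdiff(seq_len(p), bad)
  if (length(good) < 3) stop("need at least 3 good channels to interpolate")
  sol <- .spline_solve_matrix(montage$positions[good, , drop = FALSE],
                              m = m, lambda = lambda, nterms = nterms)
  cd <- sol %*% data[good, , drop = FALSE]      # (pg+1) x time
  ng <- length(good)
  cosbg <- montage$positions[bad, , drop = FALSE] %*%
    t(montage$positions[good, , drop = FALSE])
  Gbg <- .spline_gh(cosbg, m = m, nterms = nterms)$g
  est <- Gbg %*% cd[seq_len(ng), , drop = FALSE] +
    rep(1, length(bad)) %*% cd[ng + 1, , drop = FALSE]
  out <- data
  out[bad, ] <- est
  out
}

#' Surface-Laplacian current source density transform matrix
#'
#' Linear operator `T` such that `T %*% v` is the spherical-spline surface
#' Laplacian of the scalp potential vector `v` at every montage channel, in
#' uV/m^2 for a head of radius `head_radius` metres. The transform is
#' reference-free: adding a constant to `v` leaves `T %*% v` unchanged.
#'
#' @inheritParams spline_interpolate
#' @param head_radius Sphere radius in metres used to scale from the unit
#'   sphere to physical curvature (default 0.085 m).
#' @return channels x channels matrix.
#' @export
csd_transform <- function(montage, m = 4, lambda = 1e-5, nterms = 50,
                          head_radius = 0.085) {
  pos <- montage$positions
  p <- nrow(pos)
  sol <- .spline_solve_matrix(pos, m = m, lambda = lambda, nterms = nterms)
  H <- .spline_gh(tcrossprod(pos), m = m, nterms = nterms)$h
  # laplacian of sum_i c_i g(x.x_i) + d  is  -sum_i c_i h(x.x_i)
  -(H %*% sol[seq_len(p), , drop = FALSE]) / head_radius^2
}

#' Surface-Laplacian CSD of an epoch set
#'
#' Applies the spherical-spline surface Laplacian per time sample, turning
#' referenced scalp potentials (uV) into reference-free current source
#' density estimates (uV/m^2). Spatially constant potentials map to zero and
#' the result is invariant to the recording reference.
#'
#' @param epochs An [eeg_epochs] object with `units == "potential"`.
#' @inheritParams csd_transform
#' @return An [eeg_epochs] object with `units == "csd"`.
#' @export
surface_laplacian_csd <- function(epochs, montage, m = 4, lambda = 1e-5,
                                  nterms = 50, head_radius = 0.085) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!identical(epochs$channels, montage$labels)) {
    stop("epoch channels do not match montage")
  }
  if (identical(epochs$units, "csd")) stop("epochs are already in CSD units")
  Tm <- csd_transform(montage, m = m, lambda = lambda, nterms = nterms,
                      head_radius = head_radius)
  d <- epochs$data
  dm <- dim(d)
  # channels dimension is the 2nd: fold trials/time together
  flat <- matrix(aperm(d, c(2, 1, 3)), nrow = dm[2])
  out <- Tm %*% flat
  res <- aperm(array(out, dim = c(dm[2], dm[1], dm[3])), c(2, 1, 3))
  epochs$data <- res
  epochs$units <- "csd"
  epochs$history <- c(epochs$history, "csd")
  epochs
}

# --- montage I/O -----------------------------------------------------------

#' Read and write montages as JSON
#'
#' The JSON layout stores `labels`, an `n x 3` `positions` array, and the
#' reference/ground labels.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @return `read_montage_json` returns an `eeg_montage`.
#' @export
write_montage_json <- function(montage, path) {
  jsonlite::write_json(list(labels = montage$labels,
                            positions = unname(montage$positions),
                            reference_label = montage$reference_label,
                            ground_label = montage$ground_label),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_montage(x$labels, x$positions, x$reference_label, x$ground_label)
}

#' Read a whitespace-delimited electrode position file
#'
#' Accepts `.sfp`-style files (`label x y z` per line; comment lines starting
#' with `#` ignored) and normalizes the positions onto the unit sphere.
#'
#' @param path File path.
#' @param reference_label,ground_label Passed to [new_montage()].
#' @return An `eeg_montage`.
#' @export
read_montage_sfp <- function(path, reference_label = "FCz",
                             ground_label = "Fpz") {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  new_montage(tab$label, as.matrix(tab[, c("x", "y", "z")]),
              reference_label = reference_label,
              ground_label = ground_label, normalize = TRUE)
}
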