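#' Compactness of the cell mass
#'
#' Computes the convex hull of the centres of all cell-occupied sites
#' (identifier > 0), counts the lattice sites whose centre lies inside
#' or on the hull polygon (`a_hull`), and returns the ratio
#' `a_cells / a_hull` where `a_cells` is the number of cell sites. A
#' solid convex shape has compactness exactly 1; networks with lacunae
#' score low. Hull membership uses exact integer arithmetic (sites on
#' the hull boundary count as inside), so the measure is invariant
#' under translation and 90-degree rotation. Degenerate configurations
#' (all cell sites collinear) fall back to counting the lattice points
#' on the segment.
#'
#' @param image Integer label matrix (0 = ECM, > 0 = cell identifiers);
#'   the interior image, without the border frame.
#' @return List with `a_cells`, `a_hull` and `compactness`.
#' @examples
#' img <- make_fixture("square", side = 10)
#' compactness(img)$compactness  # exactly 1
#' @export
compactness <- function(image) {
  image <- .as_label_image(image)
  cells <- which(image > 0, arr.ind = TRUE)
  if (nrow(cells) == 0)
    stop("compactness is undefined for an image without cell sites")
  a_cells <- nrow(cells)
  a_hull <- .hull_site_count(cells)
  list(a_cells = a_cells, a_hull = a_hull,
       compactness = a_cells / a_hull)
}

.as_label_image <- function(image) {
  image <- as.matrix(image)
  storage.mode(image) <- "integer"
  if (any(image < 0)) stop("label image must not contain the border frame")
  image
}

# Count lattice sites with centre inside or on the convex hull of the
# given integer points. Exact: all tests are integer cross products.
.hull_site_count <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) == 1) return(1L)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # (x, y) = (col, row)
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) <= 2) {
    # collinear: lattice points on the longest segment between extremes
    d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    dr <- abs(pts[ij[1], 1] - pts[ij[2], 1])
    dc <- abs(pts[ij[1], 2] - pts[ij[2], 2])
    g <- .gcd(dr, dc)
    return(as.integer(g + 1L))
  }
  rr <- range(poly[, 1]); cc <- range(poly[, 2])
  grid <- expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2])
  inside <- rep(TRUE, nrow(grid))
  nv <- nrow(poly)
  # chull() returns the vertices clockwise in (x, y); with our
  # (col, row) call the sign convention is fixed by one orientation test
  orient <- 0
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    k <- if (j == nv) 1L else j + 1L
    o <- (poly[j, 2] - poly[i, 2]) * (poly[k, 1] - poly[i, 1]) -
         (poly[j, 1] - poly[i, 1]) * (poly[k, 2] - poly[i, 2])
    if (o != 0) { orient <- sign(o); break }
  }
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cr <- (poly[j, 2] - poly[i, 2]) * (grid$r - poly[i, 1]) -
          (poly[j, 1] - poly[i, 1]) * (grid$c - poly[i, 2])
    inside <- inside & (orient * cr >= 0)
  }
  sum(inside)
}

.gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Count enclosed lacunae
#'
#' Lacunae are patches of medium (4-connected components of identifier
#' 0) fully enclosed by cells, i.e. not 4-connected to the medium
#' component touching the image border. A lacuna is counted only when it
#' holds at least `min_size` sites (one cell area, 50 sites at the
#' reference scale). The measure depends only on occupancy, never on
#' which cell surrounds a hole, and the 4-connectivity of the medium is
#' the standard dual of the 8-neighbourhood used for cell dynamics, so
#' diagonal cell walls do not leak.
#'
#' @param image Integer label matrix (interior, no frame).
#' @param min_size Minimum lacuna size in sites (default 50).
#' @return Integer count.
#' @examples
#' ring <- make_fixture("ring", outer = 20, hole = 10)
#' lacuna_count(ring)  # one 100-site lacuna
#' @export
lacuna_count <- function(image, min_size = 50) {
  image <- .as_label_image(image)
  lab <- .label_ecm(image)
  if (max(lab) == 0) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  enclosed <- setdiff(which(sizes > 0), border)
  sum(sizes[enclosed] >= min_size)
}

#' Measure a label image
#'
#' One-row data frame with the full measure record: `a_cells`, `a_hull`,
#' `compactness` and `lacuna_count`.
#'
#' @inheritParams lacuna_count
#' @return A one-row data frame.
#' @export
measure_image <- function(image, min_size = 50) {
  cp <- compactness(image)
  data.frame(a_cells = cp$a_cells, a_hull = cp$a_hull,
             compactness = cp$compactness,
             lacuna_count = lacuna_count(image, min_size = min_size))
}

#' Synthetic label-image fixtures with known measure values
#'
#' Deterministic geometric test images whose compactness and lacuna
#' count are known by construction. The ground truth is attached as the
#' `"truth"` attribute (fields `a_cells`, `a_hull`, `hole_sites`,
#' `n_holes`).
#'
#' Shapes: `"disc"` (solid disc, radius `radius`), `"square"` (solid
#' `side x side` block), `"ring"` (square annulus, outer side `outer`,
#' centred square hole of side `hole`), `"holes"` (solid block with an
#' `k x k` grid of square holes of side `hole`), `"c_shape"` (a ring
#' whose hole is opened to the exterior by a channel), `"specks"`
#' (single-site cells at the four corners of a `side x side` square).
#'
#' @param shape One of the shape names above.
#' @param size Canvas side length (default large enough for the shape).
#' @param radius,side,outer,hole,k Shape dimensions in sites.
#' @return Integer label matrix with a `"truth"` attribute.
#' @export
make_fixture <- function(shape = c("disc", "square", "ring", "holes",
                                   "c_shape", "specks"),
                         size = NULL, radius = 10, side = 10,
                         outer = 20, hole = 10, k = 2) {
  shape <- match.arg(shape)
  place <- function(canvas, r0, c0, h, w, value = 1L) {
    canvas[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- value
    canvas
  }
  truth <- list()
  if (shape == "disc") {
    if (is.null(size)) size <- 2L * radius + 5L
    img <- matrix(0L, size, size)
    ctr <- (size + 1) / 2
    d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
    img[d2 <= radius^2] <- 1L
    truth <- list(a_cells = sum(img > 0), a_hull = sum(img > 0),
                  hole_sites = 0L, n_holes = 0L)
  } else if (shape == "square") {
    if (is.null(size)) size <- side + 4L
    img <- place(matrix(0L, size, size), 3L, 3L, side, side)
    truth <- list(a_cells = side^2, a_hull = side^2,
                  hole_sites = 0L, n_holes = 0L)
  } else if (shape == "ring") {
    if (hole > outer - 2L) stop("hole does not fit inside the ring")
    if (is.null(size)) size <- outer + 4L
    img <- place(matrix(0L, size, size), 3L, 3L, outer, outer)
    off <- 3L + (outer - hole) %/% 2L
    img <- place(img, off, off, hole, hole, 0L)
    truth <- list(a_cells = outer^2 - hole^2, a_hull = outer^2,
                  hole_sites = hole^2, n_holes = 1L)
  } else if (shape == "holes") {
    cellw <- hole + 3L
    outer_side <- k * cellw + 3L
    if (is.null(size)) size <- outer_side + 4L
    img <- place(matrix(0L, size, size), 3L, 3L, outer_side, outer_side)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      img <- place(img, 3L + 3L + (i - 1L) * cellw,
                   3L + 3L + (j - 1L) * cellw, hole, hole, 0L)
    }
    truth <- list(a_cells = outer_side^2 - k^2 * hole^2,
                  a_hull = outer_side^2,
                  hole_sites = hole^2, n_holes = as.integer(k^2))
  } else if (shape == "c_shape") {
    if (is.null(size)) size <- outer + 4L
    img <- place(matrix(0L, size, size), 3L, 3L, outer, outer)
    off <- 3L + (outer - hole) %/% 2L
    img <- place(img, off, off, hole, hole, 0L)
    # channel from the hole to the exterior: opens the enclosure
    mid <- off + hole %/% 2L
    img[mid, 1:off] <- 0L
    truth <- list(a_cells = sum(img > 0), a_hull = NA_integer_,
                  hole_sites = hole^2, n_holes = 0L)
  } else { # specks
    if (is.null(size)) size <- side + 4L
    img <- matrix(0L, size, size)
    img[3L, 3L] <- 1L
    img[3L, 3L + side - 1L] <- 2L
    img[3L + side - 1L, 3L] <- 3L
    img[3L + side - 1L, 3L + side - 1L] <- 4L
    truth <- list(a_cells = 4L, a_hull = as.integer(side^2),
                  hole_sites = 0L, n_holes = 0L)
  }
  attr(img, "truth") <- truth
  img
}

#' Read and write label images as plain text
#'
#' The exact-round-trip text dialect: whitespace-separated integers,
#' one lattice row per line. `write_chem_matrix()` uses the same layout
#' with full-precision floating-point values.
#'
#' @param image Integer (or numeric) matrix.
#' @param path File path.
#' @return The writers return `path` invisibly; the readers return a
#'   matrix.
#' @export
write_label_matrix <- function(image, path) {
  utils::write.table(as.matrix(image), path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_label_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_label_matrix
#' @export
write_chem_matrix <- function(image, path) {
  m <- format(as.matrix(image), digits = 17, scientific = TRUE,
              trim = TRUE)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_label_matrix
#' @export
read_chem_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write a label image as a 16-bit grey PNG
#'
#' Identifiers are stored as intensities `id / 65535`; requires the
#' `png` package. The text dialect ([write_label_matrix()]) remains the
#' lossless interchange format.
#'
#' @param image Integer label matrix.
#' @param path File path.
#' @export
write_label_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  m <- as.matrix(image)
  if (any(m < 0) || any(m > 65535)) stop("identifiers must be in 0..65535")
  png::writePNG(m / 65535, path)
  invisible(path)
}
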