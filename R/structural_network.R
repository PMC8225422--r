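# The fixed structural network: one periodic spatial domain per neuron on a
# global periodic plane, with domain overlaps defining the physical wiring.

.check_domain <- function(dom, d = NULL) {
  if (!is.list(dom) || is.null(dom$lower) || is.null(dom$upper))
    stop("a domain must be a list with 'lower' and 'upper'")
  lo <- as.numeric(dom$lower); up <- as.numeric(dom$upper)
  if (length(lo) != length(up) || any(!is.finite(c(lo, up))))
    stop("domain bounds must be finite vectors of equal length")
  if (any(lo >= up)) stop("domain 'lower' must be < 'upper' componentwise")
  if (!is.null(d) && length(lo) != d)
    stop("all domains must share the same spatial dimension")
  list(lower = lo, upper = up)
}

#' Structural network from spatial domains
#'
#' Each neuron owns an axis-aligned box (its dendritic/axonal territory) on a
#' global periodic plane of side `global_L`; two neurons are physically wired
#' whenever their boxes intersect under periodic wrapping (boundary touching
#' counts).  The resulting 0/1 overlap graph is the fixed structural network
#' that constrains the evolving functional couplings.
#'
#' @param domains A list of domains, each a list with numeric `lower` and
#'   `upper` vectors (componentwise `lower < upper`), in global coordinates.
#' @param global_L Side length of the global periodic plane (default 100).
#' @return An object of class `structural_network` with elements `domains`,
#'   `global_L`, `d` (spatial dimension) and `overlap` (symmetric 0/1 matrix
#'   with zero diagonal).
#' @seealso [build_lattice()] for the regular-lattice construction.
#' @export
structural_network <- function(domains, global_L = 100) {
  if (length(domains) < 1L) stop("need at least one domain")
  d <- length(as.numeric(domains[[1]]$lower))
  domains <- lapply(domains, .check_domain, d = d)
  ov <- domain_overlaps(domains, global_L)
  structure(list(domains = domains, global_L = global_L, d = d,
                 overlap = ov),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  cat(sprintf("structural_network: %d neurons, d = %d, plane side L = %g\n",
              length(x$domains), x$d, x$global_L))
  cat(sprintf("  overlap graph: %d edges, degrees %s\n",
              sum(x$overlap) / 2,
              paste(range(rowSums(x$overlap)), collapse = "..")))
  invisible(x)
}

# Circular (wrapped) distance between two scalars on a ring of length L.
.circ_dist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

#' Pairwise domain overlaps on the periodic plane
#'
#' Two axis-aligned boxes on the global torus intersect iff, on every axis,
#' the circular distance between their centers does not exceed the sum of
#' their half-widths (boundary touching counts as overlap).
#'
#' @param domains List of domains (see [structural_network()]).
#' @param global_L Side length of the global periodic plane.
#' @return Symmetric 0/1 integer matrix with zero diagonal.
#' @export
domain_overlaps <- function(domains, global_L) {
  n <- length(domains)
  d <- length(domains[[1]]$lower)
  centers <- t(vapply(domains, function(dm) (dm$lower + dm$upper) / 2,
                      numeric(d)))
  halfw <- t(vapply(domains, function(dm) (dm$upper - dm$lower) / 2,
                    numeric(d)))
  ov <- matrix(0L, n, n)
  if (n < 2L) return(ov)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      hit <- TRUE
      for (ax in seq_len(d)) {
        dc <- .circ_dist(centers[i, ax], centers[j, ax], global_L)
        # tiny tolerance so exact boundary contact survives rounding
        if (dc > halfw[i, ax] + halfw[j, ax] + 1e-9) { hit <- FALSE; break }
      }
      if (hit) ov[i, j] <- ov[j, i] <- 1L
    }
  }
  ov
}

#' Regular-lattice structural network
#'
#' Builds the `sqrt(N) x sqrt(N)` lattice of per-neuron domains on the torus.
#' Domains are axis-aligned rectangles in a checkerboard of alternating
#' orientation: cells of one parity are elongated along x, the other along y
#' (long side `spacing * (1 + overlap_fraction)`, short side
#' `spacing * (1 - overlap_fraction/2)` with `spacing = global_L / sqrt(N)`).
#' Each rectangle then overlaps exactly its four lattice neighbours and no
#' diagonal neighbour, so for even `sqrt(N)` the overlap graph is the
#' 4-regular torus lattice (for the degenerate 2x2 torus opposite neighbours
#' coincide and the distinct-pair degree collapses to 2).
#'
#' @param N Number of neurons; must be a perfect square (default 64).
#' @param global_L Side length of the global periodic plane.
#' @param overlap_fraction Fractional elongation of the long side, in (0, 1).
#' @return A [structural_network()] object; neuron `(ix, iy)` of the grid has
#'   index `(iy - 1) * sqrt(N) + ix`.
#' @export
build_lattice <- function(N = 64, global_L = 100, overlap_fraction = 0.25) {
  k <- as.integer(round(sqrt(N)))
  if (k * k != N) stop(sprintf("'N' must be a perfect square (got %d)", N))
  if (!is.numeric(overlap_fraction) || overlap_fraction <= 0 ||
      overlap_fraction >= 1)
    stop("'overlap_fraction' must lie in (0, 1)")
  spacing <- global_L / k
  long <- spacing * (1 + overlap_fraction) / 2   # half-widths
  short <- spacing * (1 - overlap_fraction / 2) / 2
  domains <- vector("list", N)
  for (iy in seq_len(k)) {
    for (ix in seq_len(k)) {
      ctr <- c((ix - 0.5) * spacing, (iy - 0.5) * spacing)
      hw <- if ((ix + iy) %% 2 == 0) c(long, short) else c(short, long)
      domains[[(iy - 1L) * k + ix]] <- list(lower = ctr - hw,
                                            upper = ctr + hw)
    }
  }
  net <- structural_network(domains, global_L = global_L)
  attr(net, "type") <- "lattice"
  attr(net, "overlap_fraction") <- overlap_fraction
  net
}

#' Wrap a position into a domain
#'
#' Periodic reduction of a position into the half-open box
#' `[lower, upper)` of a domain: the result is congruent to `position`
#' modulo the domain's side lengths.  Idempotent, and deterministic at the
#' boundary (`upper` maps to `lower`).
#'
#' @param position Numeric vector (or matrix, one row per point).
#' @param domain A domain list with `lower` and `upper`.
#' @return Wrapped position(s), same shape as `position`.
#' @export
wrap_position <- function(position, domain) {
  lo <- domain$lower; side <- domain$upper - domain$lower
  if (is.matrix(position)) {
    sweep(sweep(position, 2, lo) %% rep(side, each = nrow(position)),
          2, lo, `+`)
  } else {
    lo + (position - lo) %% side
  }
}

#' Serialize a structural network to a text file
#'
#' Writes a JSON header line (prefixed `#`) holding the plane size and the
#' domain geometry, followed by the overlap graph as one 0-based `i j` edge
#' per line.
#'
#' @param network A [structural_network()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structural_network <- function(network, path) {
  header <- sprintf(
    '# {"global_L": %s, "d": %d, "lower": [%s], "upper": [%s]}',
    format(network$global_L, digits = 15), network$d,
    paste(vapply(network$domains, function(dm)
      paste0("[", paste(format(dm$lower, digits = 15), collapse = ","), "]"),
      character(1)), collapse = ","),
    paste(vapply(network$domains, function(dm)
      paste0("[", paste(format(dm$upper, digits = 15), collapse = ","), "]"),
      character(1)), collapse = ","))
  edges <- which(upper.tri(network$overlap) & network$overlap == 1L,
                 arr.ind = TRUE)
  lines <- c(header,
             sprintf("%d %d", edges[, 1] - 1L, edges[, 2] - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structural network written by [write_structural_network()]
#'
#' @param path Input file path.
#' @return A [structural_network()] object (the overlap graph is recomputed
#'   from the stored geometry and checked against the stored edge list).
#' @export
read_structural_network <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ", "", lines[1])
  # minimal JSON pull-out without adding a hard dependency
  meta <- if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::fromJSON(hdr, simplifyVector = TRUE)
  } else {
    stop("reading structural networks requires the 'jsonlite' package")
  }
  n <- nrow(meta$lower)
  domains <- lapply(seq_len(n), function(i)
    list(lower = as.numeric(meta$lower[i, ]),
         upper = as.numeric(meta$upper[i, ])))
  net <- structural_network(domains, global_L = meta$global_L)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body)) {
    ij <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.integer)) + 1L
    stored <- matrix(0L, n, n)
    stored[ij] <- 1L
    stored <- stored | t(stored)
    if (!identical(unname(stored * 1L), unname(net$overlap * 1L)))
      warning("stored edge list disagrees with recomputed overlaps")
  }
  net
}
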