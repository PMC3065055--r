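#' Generate the irregular automaton lattice
#'
#' Builds the cellular-automaton lattice as the Voronoi tessellation of a
#' random-sequential-addition (RSA) hard-disk point process, clipped to a
#' rectangular tissue domain. Each automaton cell stands for a cluster of
#' about seven glial cells (glial diameter ~40 um), giving a target
#' equivalent cell diameter of about 106 um -- below the 250 um oxygen
#' diffusion length, so a cell is either oxygenated or not as a whole.
#'
#' The RSA hard-disk diameter is `rsa_factor * target_cell_diameter`; the
#' default 0.8 calibration gives post-tessellation mean cell diameters
#' within a few percent of the target on saturated packings.
#'
#' @param domain_extent numeric length-2, domain width and height in mm.
#' @param target_cell_diameter target equivalent cell diameter in um.
#' @param seed integer RNG seed; generation is reproducible bit-for-bit.
#' @param rsa_factor hard-disk diameter as a fraction of the target cell
#'   diameter.
#' @param attempt_budget maximum number of RSA proposals.
#' @param patience consecutive rejections after which the packing is
#'   declared saturated.
#' @return an object of class `automaton_lattice`: centers (mm), clipped
#'   Voronoi polygons (mm), cell areas (mm^2), symmetric adjacency,
#'   per-cell nearest neighbour, and the domain extent.
#' @export
generate_lattice <- function(domain_extent = c(20, 20),
                             target_cell_diameter = 105.9,
                             seed = 1L,
                             rsa_factor = 0.8,
                             attempt_budget = 5e6,
                             patience = 1e5) {
  if (length(domain_extent) != 2L || any(!is.finite(domain_extent)) ||
      any(domain_extent <= 0)) {
    stop("invalid argument: domain_extent must be two positive lengths (mm)")
  }
  if (!is.finite(target_cell_diameter) || target_cell_diameter <= 0) {
    stop("invalid argument: target_cell_diameter must be positive (um)")
  }
  w <- domain_extent[1]
  h <- domain_extent[2]
  td_mm <- target_cell_diameter / 1000
  disk <- rsa_factor * td_mm
  area <- w * h
  n_target <- max(1L, ceiling(area / (pi * (td_mm / 2)^2)))
  # jamming coverage of 2-D RSA disks is ~0.547; 90% of the smaller of the
  # two implied densities is the generation-failure threshold
  n_sat <- 0.547 * area / (pi * (disk / 2)^2)

  set.seed(seed)
  centers <- rsa_disks_cpp(w, h, disk, as.integer(n_target),
                           as.integer(attempt_budget), as.integer(patience))
  n <- nrow(centers)
  if (n < 1L) stop("generation failure: RSA produced no points")
  if (n < 0.9 * min(n_target, n_sat)) {
    stop(sprintf(paste0("generation failure: RSA reached %d points, under ",
                        "90%% of the implied density (target %d, ",
                        "saturation estimate %.0f); increase attempt_budget"),
                 n, n_target, n_sat))
  }

  vor <- voronoi_cpp(centers[, 1], centers[, 2], 0, w, 0, h)
  adj <- symmetrize_adjacency(vor$neighbors)
  areas <- vor$areas

  cover <- sum(areas)
  if (abs(cover - area) > 1e-3 * area) {
    stop(sprintf("internal error: tessellation covers %.6f of %.6f mm^2",
                 cover, area))
  }

  nn <- nearest_neighbor_of(centers, adj)
  deg <- lengths(adj)
  lat <- structure(
    list(centers = centers,
         adj_ptr = c(0L, cumsum(deg)),
         adj_idx = unlist(adj, use.names = FALSE),
         polygons = vor$polygons,
         areas = areas,
         adjacency = adj,
         nearest_neighbor = nn,
         domain = c(width = w, height = h),
         target_cell_diameter = target_cell_diameter,
         rsa_factor = rsa_factor,
         disk_diameter = disk,
         mean_diameter = mean(2 * sqrt(areas / pi)) * 1000, # um
         seed = seed,
         n = n),
    class = "automaton_lattice")
  lat
}

symmetrize_adjacency <- function(nbrs) {
  n <- length(nbrs)
  from <- rep.int(seq_len(n), lengths(nbrs))
  to <- unlist(nbrs, use.names = FALSE)
  keep <- from != to
  from <- from[keep]
  to <- to[keep]
  a <- c(from, to)
  b <- c(to, from)
  split(b, factor(a, levels = seq_len(n))) |>
    lapply(function(v) sort(unique(v)))
}

nearest_neighbor_of <- function(centers, adj) {
  vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0L) return(NA_integer_)
    d2 <- (centers[nb, 1] - centers[i, 1])^2 +
      (centers[nb, 2] - centers[i, 2])^2
    nb[which.min(d2)]
  }, integer(1))
}

#' Directed chain of adjacent cells
#'
#' Starting from `start_cell`, repeatedly steps to the adjacent cell whose
#' center best continues `direction` (maximal cosine; ties broken by lowest
#' cell id; only steps with a positive projection are taken, so the walk
#' always advances and terminates). The walk stops when no neighbour
#' advances (the domain boundary) or, if `stop_at` is given, on the first
#' cell for which `stop_at` is `TRUE` -- the cell-division push uses this to
#' find the first non-tumour cell along the outward ray.
#'
#' @param lattice an `automaton_lattice`.
#' @param start_cell starting cell id.
#' @param direction numeric length-2 direction (need not be normalised).
#' @param stop_at optional logical vector over cells; the chain ends when it
#'   reaches a cell with `stop_at[cell]` TRUE (that cell is included).
#' @return integer vector of cell ids, beginning with `start_cell`.
#' @export
nearest_neighbor_chain <- function(lattice, start_cell, direction,
                                   stop_at = NULL) {
  n <- lattice$n
  if (!(start_cell %in% seq_len(n))) {
    stop("invalid argument: start_cell out of range")
  }
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm <= 0) {
    stop("invalid argument: direction must be a nonzero vector")
  }
  direction <- direction / nrm
  cx <- lattice$centers[, 1]
  cy <- lattice$centers[, 2]
  chain <- integer(64)
  chain[1] <- start_cell
  len <- 1L
  cur <- start_cell
  repeat {
    if (!is.null(stop_at) && stop_at[cur]) break
    nb <- lattice$adjacency[[cur]]
    dx <- cx[nb] - cx[cur]
    dy <- cy[nb] - cy[cur]
    proj <- dx * direction[1] + dy * direction[2]
    cosv <- proj / sqrt(dx^2 + dy^2)
    ok <- which(proj > 0)
    if (length(ok) == 0L) break
    best <- ok[order(-cosv[ok], nb[ok])][1]
    cur <- nb[best]
    len <- len + 1L
    if (len > length(chain)) chain <- c(chain, integer(length(chain)))
    chain[len] <- cur
    if (len > n) stop("internal error: chain exceeded lattice size")
  }
  chain[seq_len(len)]
}

#' Tabular view of a lattice
#'
#' One row per automaton cell: id, center coordinates (mm), area (mm^2) and
#' the comma-separated neighbour list. Suitable for plain-text round trips
#' with [utils::write.table()].
#' @param lattice an `automaton_lattice`.
#' @export
lattice_table <- function(lattice) {
  data.frame(
    id = seq_len(lattice$n),
    x = lattice$centers[, 1],
    y = lattice$centers[, 2],
    area = lattice$areas,
    neighbors = vapply(lattice$adjacency, paste, collapse = ",",
                       FUN.VALUE = character(1)),
    stringsAsFactors = FALSE)
}

#' @export
as.data.frame.automaton_lattice <- function(x, ...) lattice_table(x)

#' @export
print.automaton_lattice <- function(x, ...) {
  cat(sprintf(paste0("automaton lattice: %d cells on %.1f x %.1f mm, mean ",
                     "equivalent diameter %.1f um (target %.1f um)\n"),
              x$n, x$domain[1], x$domain[2], x$mean_diameter,
              x$target_cell_diameter))
  invisible(x)
}
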