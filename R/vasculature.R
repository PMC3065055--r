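#' Placement constraints for the healthy microvascular network
#'
#' The healthy capillary bed is a randomized Krogh-type network: straight
#' vessels placed sequentially under three constraints -- a candidate may not
#' run too close to a roughly parallel accepted vessel, may not make too many
#' vessels meet at one site, and must bring at least one previously
#' unvascularized cell within the oxygen diffusion length.
#'
#' @param min_parallel_spacing minimum distance (um) to an accepted vessel
#'   whose orientation differs by less than `parallel_tol_deg`.
#' @param max_vessels_per_site maximum number of distinct vessels passing
#'   through one automaton cell site.
#' @param l_prolif vascularization radius (um): a cell within this distance
#'   of a vessel is considered supplied. 250 um is the characteristic
#'   diffusion length of oxygen in tissue.
#' @param attempt_budget maximum number of candidate vessels tried.
#' @param parallel_tol_deg orientation difference (degrees) under which two
#'   vessels count as parallel.
#' @export
vessel_placement_params <- function(min_parallel_spacing = 80,
                                    max_vessels_per_site = 3,
                                    l_prolif = 250,
                                    attempt_budget = 20000,
                                    parallel_tol_deg = 10) {
  p <- list(min_parallel_spacing = min_parallel_spacing,
            max_vessels_per_site = max_vessels_per_site,
            l_prolif = l_prolif,
            attempt_budget = attempt_budget,
            parallel_tol_deg = parallel_tol_deg)
  if (any(vapply(p[-4], function(z) !is.finite(z) || z <= 0, logical(1))) ||
      attempt_budget < 0) {
    stop("invalid argument: all vessel placement parameters must be positive")
  }
  structure(p, class = "vessel_placement_params")
}

# intersection of the infinite line through `anchor` with direction theta
# and the rectangle [0,w] x [0,h]; NULL if it misses
clip_line_to_rect <- function(anchor, theta, w, h) {
  d <- c(cos(theta), sin(theta))
  ts <- c(-Inf, Inf)
  p <- anchor
  # Liang-Barsky on t in (-inf, inf)
  lo <- -1e9
  hi <- 1e9
  for (k in 1:2) {
    lim <- if (k == 1) w else h
    if (abs(d[k]) < 1e-12) {
      if (p[k] < 0 || p[k] > lim) return(NULL)
    } else {
      t1 <- (0 - p[k]) / d[k]
      t2 <- (lim - p[k]) / d[k]
      lo <- max(lo, min(t1, t2))
      hi <- min(hi, max(t1, t2))
    }
  }
  if (lo >= hi) return(NULL)
  rbind(p + lo * d, p + hi * d)
}

# minimum distance between two segments (each a 2x2 matrix of endpoints)
seg_seg_distance <- function(s1, s2) {
  or <- function(p, q, r) {
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  }
  if (or(s1[1, ], s1[2, ], s2[1, ]) * or(s1[1, ], s1[2, ], s2[2, ]) < 0 &&
      or(s2[1, ], s2[2, ], s1[1, ]) * or(s2[1, ], s2[2, ], s1[2, ]) < 0) {
    return(0)
  }
  min(dist_points_one_segment_cpp(s2[, 1], s2[, 2],
                                  s1[1, 1], s1[1, 2], s1[2, 1], s1[2, 2]),
      dist_points_one_segment_cpp(s1[, 1], s1[, 2],
                                  s2[1, 1], s2[1, 2], s2[2, 1], s2[2, 2]))
}

empty_network <- function(lattice, sub_len) {
  structure(
    list(ax = numeric(0), ay = numeric(0), bx = numeric(0), by = numeric(0),
         type = integer(0),        # 1 = native, 2 = angiogenic
         alive = logical(0),
         parent = integer(0),      # NA for flow roots (trunk sources)
         child_count = integer(0),
         tip_open = logical(0),
         creation_day = numeric(0),
         trunk = integer(0),
         n = 0L,
         trunks = data.frame(id = integer(0), theta = numeric(0),
                             ax = numeric(0), ay = numeric(0),
                             bx = numeric(0), by = numeric(0),
                             newly_vascularized = integer(0)),
         sub_len = sub_len,
         domain = lattice$domain,
         cell_x = lattice$centers[, 1],
         cell_y = lattice$centers[, 2],
         cell_dist = rep.int(Inf, lattice$n),   # mm, to nearest alive segment
         cell_nearest = rep.int(NA_integer_, lattice$n)),
    class = "vessel_network")
}

#' Generate the healthy microvascular network
#'
#' Sequentially samples straight candidate vessels (uniform anchor, uniform
#' orientation on `[0, pi)`, clipped to the domain) and accepts them under
#' the constraints in [vessel_placement_params()]. Placement stops when every
#' automaton cell lies within `l_prolif` of a vessel or the attempt budget is
#' exhausted; incomplete coverage gives a warning (uncovered healthy cells
#' will die by the automaton's apoptosis rule). Accepted vessels are
#' discretized into sub-segments no longer than the mean lattice cell
#' diameter, the unit at which regression and disruption checks act. Each
#' trunk carries blood from its first endpoint (its boundary source), so a
#' destroyed sub-segment starves everything downstream of it -- the upstream
#' cascade that shapes both avascular growth arrest and the response to
#' vascular disruption.
#'
#' @param lattice an `automaton_lattice`.
#' @param params a `vessel_placement_params`.
#' @param seed integer RNG seed.
#' @return a `vessel_network` carrying, per sub-segment, endpoints (mm),
#'   type, alive flag, flow parent and creation day, plus the per-cell
#'   distance cache used by the automaton rules.
#' @export
generate_native_network <- function(lattice, params = vessel_placement_params(),
                                    seed = 1L) {
  stopifnot(inherits(lattice, "automaton_lattice"))
  w <- lattice$domain[["width"]]
  h <- lattice$domain[["height"]]
  sub_len <- lattice$mean_diameter / 1000 # mm
  lp <- params$l_prolif / 1000            # mm
  spacing <- params$min_parallel_spacing / 1000
  ptol <- params$parallel_tol_deg * pi / 180
  r_site <- sub_len / 2

  net <- empty_network(lattice, sub_len)
  cx <- lattice$centers[, 1]
  cy <- lattice$centers[, 2]
  site_count <- integer(lattice$n)

  set.seed(seed)
  attempts <- 0L
  while (attempts < params$attempt_budget && any(net$cell_dist > lp)) {
    attempts <- attempts + 1L
    theta <- runif(1, 0, pi)
    anchor <- c(runif(1, 0, w), runif(1, 0, h))
    seg <- clip_line_to_rect(anchor, theta, w, h)
    if (is.null(seg)) next

    # (a) spacing to parallel accepted vessels
    tr <- net$trunks
    if (nrow(tr) > 0) {
      dth <- abs(tr$theta - theta)
      dth <- pmin(dth, pi - dth)
      par_ids <- which(dth < ptol)
      bad <- FALSE
      for (j in par_ids) {
        s2 <- rbind(c(tr$ax[j], tr$ay[j]), c(tr$bx[j], tr$by[j]))
        if (seg_seg_distance(seg, s2) < spacing) { bad <- TRUE; break }
      }
      if (bad) next
    }

    dcand <- dist_points_one_segment_cpp(cx, cy, seg[1, 1], seg[1, 2],
                                         seg[2, 1], seg[2, 2])
    # (b) vessel crowding at automaton-cell sites
    hit <- which(dcand < r_site)
    if (any(site_count[hit] + 1L > params$max_vessels_per_site)) next
    # (c) must vascularize at least one new cell
    newly <- which(net$cell_dist > lp & dcand <= lp)
    if (length(newly) == 0L) next

    net <- add_trunk(net, seg, theta, dcand, length(newly))
    site_count[hit] <- site_count[hit] + 1L
  }

  covered <- mean(net$cell_dist <= lp)
  if (covered < 1) {
    warning(sprintf(paste0("vessel placement stopped at %.1f%% coverage ",
                           "after %d attempts (%d vessels); uncovered ",
                           "healthy cells will undergo apoptosis"),
                    100 * covered, attempts, nrow(net$trunks)))
  }
  attr(net, "attempts") <- attempts
  net
}

# append one straight trunk, discretized into sub-segments, and refresh the
# distance cache from the candidate distances already computed
add_trunk <- function(net, seg, theta, dcand, n_new) {
  len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
  nseg <- max(1L, ceiling(len / net$sub_len))
  tt <- seq(0, 1, length.out = nseg + 1L)
  px <- seg[1, 1] + tt * (seg[2, 1] - seg[1, 1])
  py <- seg[1, 2] + tt * (seg[2, 2] - seg[1, 2])
  ids <- net$n + seq_len(nseg)
  trunk_id <- nrow(net$trunks) + 1L

  net$ax <- c(net$ax, px[-length(px)])
  net$ay <- c(net$ay, py[-length(py)])
  net$bx <- c(net$bx, px[-1])
  net$by <- c(net$by, py[-1])
  net$type <- c(net$type, rep.int(1L, nseg))
  net$alive <- c(net$alive, rep.int(TRUE, nseg))
  # blood flows from the trunk's first endpoint (the boundary source):
  # sub-segment k is supplied through sub-segment k-1
  net$parent <- c(net$parent, c(NA_integer_, ids[-nseg]))
  net$child_count <- c(net$child_count, rep.int(0L, nseg))
  net$tip_open <- c(net$tip_open, rep.int(FALSE, nseg))
  net$creation_day <- c(net$creation_day, rep.int(0, nseg))
  net$trunk <- c(net$trunk, rep.int(trunk_id, nseg))
  net$n <- net$n + nseg
  net$trunks <- rbind(net$trunks,
                      data.frame(id = trunk_id, theta = theta,
                                 ax = seg[1, 1], ay = seg[1, 2],
                                 bx = seg[2, 1], by = seg[2, 2],
                                 newly_vascularized = n_new))

  # refresh the distance cache; the nearest sub-segment of an improved cell
  # is the one holding its projection onto the trunk
  ii <- which(dcand < net$cell_dist)
  if (length(ii) > 0L) {
    vx <- seg[2, 1] - seg[1, 1]
    vy <- seg[2, 2] - seg[1, 2]
    L2 <- vx^2 + vy^2
    tp <- ((net$cell_x[ii] - seg[1, 1]) * vx +
             (net$cell_y[ii] - seg[1, 2]) * vy) / L2
    tp <- pmin(pmax(tp, 0), 1)
    sub <- pmin(nseg, pmax(1L, ceiling(tp * nseg)))
    net$cell_dist[ii] <- dcand[ii]
    net$cell_nearest[ii] <- ids[sub]
  }
  net
}

#' Distance from a point to the nearest alive vessel
#'
#' Euclidean point-to-segment distance over all alive sub-segments, in um.
#' Returns `Inf` when no alive vessel exists.
#'
#' @param network a `vessel_network`.
#' @param point numeric length-2 coordinate in mm.
#' @export
distance_to_nearest_vessel <- function(network, point) {
  al <- which(network$alive)
  if (length(al) == 0L) return(Inf)
  r <- nearest_segment_cpp(point[1], point[2],
                           network$ax[al], network$ay[al],
                           network$bx[al], network$by[al])
  r$dist * 1000
}

#' Remove vessel segments together with their flow-dependency closure
#'
#' Marks the given segments dead, along with every segment whose only path
#' to a blood source runs through one of them: killing the source of blood
#' effectively destroys everything it alone supplied. Native trunks are fed
#' from the domain boundary at both ends and act as flow roots; angiogenic
#' sprouts depend on the segment they sprouted from, so the closure is the
#' descendant set in the sprout tree.
#'
#' @param network a `vessel_network`.
#' @param doomed integer ids of alive segments to destroy.
#' @return list with the updated `network`, the ids actually `removed`
#'   (including the cascade) and the total count `n_removed`.
#' @export
remove_segments_with_cascade <- function(network, doomed) {
  doomed <- unique(as.integer(doomed))
  if (length(doomed) == 0L) {
    return(list(network = network, removed = integer(0), n_removed = 0L))
  }
  if (any(doomed < 1L | doomed > network$n) || !all(network$alive[doomed])) {
    stop("invalid argument: doomed must be ids of alive segments")
  }
  # descendant closure over the sprout tree (children recovered from parent
  # pointers; only alive segments matter)
  al <- which(network$alive)
  par <- network$parent[al]
  kids <- split(al[!is.na(par)], factor(par[!is.na(par)], levels = seq_len(network$n)))
  removed <- logical(network$n)
  queue <- doomed
  removed[queue] <- TRUE
  while (length(queue) > 0L) {
    nxt <- unlist(kids[queue], use.names = FALSE)
    nxt <- nxt[!removed[nxt]]
    removed[nxt] <- TRUE
    queue <- nxt
  }
  rm_ids <- which(removed)
  network$alive[rm_ids] <- FALSE
  network$tip_open[rm_ids] <- FALSE
  # surviving parents may sprout again once their branch has died back
  # (in-trunk parentage is not counted in child_count, only sprouts)
  spr <- rm_ids[network$type[rm_ids] == 2L]
  par <- network$parent[spr]
  par <- par[!is.na(par) & !removed[par]]
  if (length(par) > 0L) {
    tb <- table(par)
    ids <- as.integer(names(tb))
    network$child_count[ids] <- pmax(0L, network$child_count[ids] -
                                       as.integer(tb))
  }

  # distance cache: removal can only increase distances, and only for cells
  # whose nearest segment died
  affected <- which(network$cell_nearest %in% rm_ids)
  if (length(affected) > 0L) {
    al2 <- which(network$alive)
    if (length(al2) == 0L) {
      network$cell_dist[affected] <- Inf
      network$cell_nearest[affected] <- NA_integer_
    } else {
      r <- nearest_segment_cpp(network$cell_x[affected],
                               network$cell_y[affected],
                               network$ax[al2], network$ay[al2],
                               network$bx[al2], network$by[al2])
      network$cell_dist[affected] <- r$dist
      network$cell_nearest[affected] <- al2[r$idx]
    }
  }
  list(network = network, removed = rm_ids, n_removed = length(rm_ids))
}

# append already-built angiogenic segments (used by sprouting)
append_segments <- function(network, ax, ay, bx, by, parent, day, tip_open) {
  k <- length(ax)
  if (k == 0L) return(list(network = network, ids = integer(0)))
  ids <- network$n + seq_len(k)
  network$ax <- c(network$ax, ax)
  network$ay <- c(network$ay, ay)
  network$bx <- c(network$bx, bx)
  network$by <- c(network$by, by)
  network$type <- c(network$type, rep.int(2L, k))
  network$alive <- c(network$alive, rep.int(TRUE, k))
  network$parent <- c(network$parent, as.integer(parent))
  network$child_count <- c(network$child_count, rep.int(0L, k))
  network$child_count[parent] <- network$child_count[parent] + 1L
  network$tip_open <- c(network$tip_open, tip_open)
  network$creation_day <- c(network$creation_day, rep.int(day, k))
  network$trunk <- c(network$trunk, rep.int(NA_integer_, k))
  network$n <- network$n + k

  for (j in seq_len(k)) {
    d <- dist_points_one_segment_cpp(network$cell_x, network$cell_y,
                                     ax[j], ay[j], bx[j], by[j])
    better <- d < network$cell_dist
    network$cell_dist[better] <- d[better]
    network$cell_nearest[better] <- ids[j]
  }
  list(network = network, ids = ids)
}

#' Tabular edge list of a vessel network
#'
#' One row per sub-segment: id, endpoints (mm), type, flow parent, alive
#' flag and creation day.
#' @param network a `vessel_network`.
#' @export
vessel_table <- function(network) {
  data.frame(id = seq_len(network$n),
             ax = network$ax, ay = network$ay,
             bx = network$bx, by = network$by,
             type = c("native", "angiogenic")[network$type],
             parent = network$parent,
             alive = network$alive,
             creation_day = network$creation_day,
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.vessel_network <- function(x, ...) vessel_table(x)

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(paste0("vessel network: %d/%d sub-segments alive ",
                     "(%d native trunks, %d angiogenic)\n"),
              sum(x$alive), x$n, nrow(x$trunks),
              sum(x$alive & x$type == 2L)))
  invisible(x)
}
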