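#' Vessel regression and sprouting parameters
#'
#' A vessel sub-segment regresses when its local bound-Ang-2 concentration
#' exceeds `regression_ratio` times bound Ang-1 (destabilization by the
#' Ang-2/Tie-2 axis) unless rescued by bound VEGF at or above `rv_crit`;
#' vessel tips with bound VEGF at or above `rv_crit` sprout one step per day
#' along the VEGF gradient.
#'
#' The default `rv_crit` and `ra2_floor` are calibrated against the steady
#' fields of a nascent hypoxic focus (a 0.25 mm radius hypoxic disk): both
#' the VEGF rescue/sprouting reach and the Ang-2 destabilization reach are
#' set to twice the oxygen diffusion length from the focus edge (see
#' [calibrate_rv_crit()] and [calibrate_ang2_floor()]). Hypoxia therefore
#' recruits and protects the vessels around it while VEGF signalling is
#' intact; suppressing the VEGF response (an angiogenesis inhibitor, or an
#' endothelium that cannot respond) leaves the bare Ang-2 destabilization
#' zone, which strips the vasculature around the tumour.
#'
#' @param regression_ratio bound-Ang-2 : bound-Ang-1 ratio marking a vessel
#'   for regression (default 6).
#' @param rv_crit bound-VEGF threshold (uM) for vessel survival and
#'   sprouting.
#' @param sprout_step sprout elongation per day (um); `NA` means one lattice
#'   sub-segment length (about one automaton cell diameter).
#' @param anastomosis_frac a sprout whose tip lands within this fraction of
#'   a sub-segment length of another alive vessel fuses with it and stops
#'   extending.
#' @param ra2_floor absolute bound-Ang-2 level (uM) below which the
#'   destabilization rule does not act on vessels outside malignant tissue.
#'   Ang-1 is secreted only by tumour-associated endothelium, so outside the
#'   tumour the ratio rule alone would fire on arbitrarily small diffused
#'   Ang-2; the floor restricts hypoxia-driven destabilization to the
#'   Ang-2 plume proper. Calibrated by [calibrate_ang2_floor()] at twice
#'   the oxygen diffusion length from a nascent hypoxic focus.
#' @param plume_hazard daily death probability of a destabilized vessel
#'   outside malignant tissue (1 = destabilization acts within the daily
#'   step, like the in-tumour rule; smaller values model slower endothelial
#'   regression under a bare Ang-2 signal).
#' @param native_regression should native vessels be subject to the
#'   regression rule? The cooption-regression-growth picture requires it;
#'   angiogenic vessels are always subject to it.
#' @param vegf_rescue should bound VEGF at `rv_crit` rescue destabilized
#'   vessels? Turned off (together with sprouting) to model a tumour whose
#'   endothelium cannot respond to VEGF at all.
#' @export
angiogenesis_params <- function(regression_ratio = 6,
                                rv_crit = 3.0e-5,
                                ra2_floor = 3.8e-5,
                                plume_hazard = 1,
                                sprout_step = NA,
                                anastomosis_frac = 0.5,
                                native_regression = TRUE,
                                vegf_rescue = TRUE) {
  if (!(regression_ratio > 0) || !(rv_crit > 0) || !(ra2_floor >= 0)) {
    stop("invalid argument: regression_ratio, rv_crit, ra2_floor must be positive")
  }
  structure(list(regression_ratio = regression_ratio, rv_crit = rv_crit,
                 ra2_floor = ra2_floor, plume_hazard = plume_hazard,
                 sprout_step = sprout_step,
                 anastomosis_frac = anastomosis_frac,
                 native_regression = native_regression,
                 vegf_rescue = vegf_rescue),
            class = "angiogenesis_params")
}

#' Daily vessel regression
#'
#' Evaluates the destabilization rule at every alive sub-segment: local
#' bound Ang-2 above `regression_ratio` times bound Ang-1, with bound VEGF
#' below `rv_crit` (no rescue), marks the segment for removal; removal
#' cascades through the flow-dependency closure
#' ([remove_segments_with_cascade()]). Inside malignant tissue the pure
#' ratio rule applies and acts within a day (cooption destabilizes the
#' endothelium before Ang-1 accumulates); outside, the rule additionally
#' requires bound Ang-2 above `ra2_floor` (the Ang-2 plume of nearby
#' hypoxic tissue) and kills with the daily probability `plume_hazard`,
#' since endothelial regression under a bare destabilizing signal takes
#' days. Native vessels are exempt altogether when `native_regression` is
#' off.
#'
#' @param rng an [rng_stream()] for the plume hazard; `NULL` makes plume
#'   death deterministic (every exposed vessel dies the same day).
#'
#' @param network a `vessel_network`.
#' @param fields a `field_state`, current for today.
#' @param indicators the `indicator_raster` used for today's PDE step
#'   (supplies the malignant-tissue mask).
#' @param params an `angiogenesis_params`.
#' @return list: updated `network`, ids `removed` (with cascade),
#'   `n_removed`.
#' @export
regress_vessels <- function(network, fields, indicators,
                            params = angiogenesis_params(), rng = NULL) {
  al <- which(network$alive)
  if (length(al) == 0L) {
    return(list(network = network, removed = integer(0), n_removed = 0L))
  }
  m <- fields$mesh
  midx <- mesh_index(m, (network$ax[al] + network$bx[al]) / 2,
                     (network$ay[al] + network$by[al]) / 2)
  ra1 <- fields$ra1[midx]
  ra2 <- fields$ra2[midx]
  rv <- fields$rv[midx]
  malignant <- (indicators$p + indicators$h + indicators$n)[midx] > 0
  # cooption destabilization inside the tumour acts within a day; the bare
  # Ang-2 plume outside kills exposed endothelium with a daily hazard
  in_plume <- !malignant & ra2 > pmax(params$regression_ratio * ra1,
                                      params$ra2_floor)
  hit <- if (is.null(rng)) {
    rep(TRUE, length(al))
  } else {
    u <- rng_draw(rng, function() runif(length(al)))
    u < params$plume_hazard
  }
  destab <- ifelse(malignant, ra2 > params$regression_ratio * ra1,
                   in_plume & hit)
  rescued <- params$vegf_rescue & rv >= params$rv_crit
  eligible <- network$type[al] == 2L | params$native_regression
  doomed <- al[destab & !rescued & eligible]
  remove_segments_with_cascade(network, doomed)
}

#' Daily angiogenic sprouting
#'
#' Every eligible sprouting site with local bound VEGF at or above
#' `rv_crit` emits one new angiogenic sub-segment of length `sprout_step`
#' along the steepest ascent of the VEGF field (central-difference
#' gradient). Eligible sites are the open tips of angiogenic segments
#' (elongation) and native sub-segments that have not branched yet
#' (sprout initiation from the coopted host vasculature). Where the local
#' gradient vanishes the sprout continues along its parent's direction
#' (angiogenic tips) or perpendicular to the trunk (native initiation). A
#' tip landing within `anastomosis_frac` of a sub-segment length of another
#' alive vessel fuses with it and stops extending; tips are clipped to the
#' domain.
#'
#' @param network a `vessel_network`.
#' @param fields a `field_state`, current for today.
#' @param params an `angiogenesis_params`.
#' @param rng an [rng_stream()] (reserved for stochastic variants; the
#'   default rule is deterministic).
#' @param day creation day recorded on new segments.
#' @return list: updated `network`, `new_ids`, `n_new`.
#' @export
sprout_vessels <- function(network, fields, params = angiogenesis_params(),
                           rng = NULL, day = 0) {
  m <- fields$mesh
  step_mm <- if (is.na(params$sprout_step)) network$sub_len else
    params$sprout_step / 1000
  w <- network$domain[["width"]]
  h <- network$domain[["height"]]

  tips_angio <- which(network$alive & network$type == 2L & network$tip_open &
                        network$child_count == 0L)
  tips_native <- which(network$alive & network$type == 1L &
                         network$child_count == 0L)
  sites <- c(tips_angio, tips_native)
  if (length(sites) == 0L) {
    return(list(network = network, new_ids = integer(0), n_new = 0L))
  }
  is_angio <- c(rep(TRUE, length(tips_angio)), rep(FALSE, length(tips_native)))
  sx <- ifelse(is_angio, network$bx[sites],
               (network$ax[sites] + network$bx[sites]) / 2)
  sy <- ifelse(is_angio, network$by[sites],
               (network$ay[sites] + network$by[sites]) / 2)
  pix <- mesh_index(m, sx, sy)
  go <- fields$rv[pix] >= params$rv_crit
  if (!any(go)) {
    return(list(network = network, new_ids = integer(0), n_new = 0L))
  }
  sites <- sites[go]; is_angio <- is_angio[go]
  sx <- sx[go]; sy <- sy[go]

  gr <- v_gradient_at(fields, sx, sy)
  nax <- nay <- nbx <- nby <- numeric(0)
  npar <- integer(0)
  nopen <- logical(0)
  for (j in seq_along(sites)) {
    g <- gr[j, ]
    gn <- sqrt(sum(g^2))
    if (gn > 0) {
      dirv <- g / gn
    } else {
      pv <- c(network$bx[sites[j]] - network$ax[sites[j]],
              network$by[sites[j]] - network$ay[sites[j]])
      pv <- pv / sqrt(sum(pv^2))
      dirv <- if (is_angio[j]) pv else c(-pv[2], pv[1])
    }
    ex <- min(w, max(0, sx[j] + step_mm * dirv[1]))
    ey <- min(h, max(0, sy[j] + step_mm * dirv[2]))
    seg_len <- sqrt((ex - sx[j])^2 + (ey - sy[j])^2)
    if (seg_len < 1e-6) next
    clipped <- seg_len < step_mm - 1e-9
    # anastomosis against all alive vessels except the parent site
    fuse <- FALSE
    alv <- which(network$alive)
    alv <- alv[alv != sites[j]]
    if (length(alv) > 0L) {
      nd <- nearest_segment_cpp(ex, ey, network$ax[alv], network$ay[alv],
                                network$bx[alv], network$by[alv])
      fuse <- nd$dist <= params$anastomosis_frac * network$sub_len
    }
    nax <- c(nax, sx[j]); nay <- c(nay, sy[j])
    nbx <- c(nbx, ex); nby <- c(nby, ey)
    npar <- c(npar, sites[j])
    nopen <- c(nopen, !fuse && !clipped)
  }
  res <- append_segments(network, nax, nay, nbx, nby, npar, day, nopen)
  list(network = res$network, new_ids = res$ids, n_new = length(res$ids))
}

# central-difference gradient of the VEGF field at arbitrary points
v_gradient_at <- function(fields, x, y) {
  m <- fields$mesh
  ix <- pmin(m$nx, pmax(1L, as.integer(floor(x / m$dx)) + 1L))
  iy <- pmin(m$ny, pmax(1L, as.integer(floor(y / m$dx)) + 1L))
  ixm <- pmax(1L, ix - 1L); ixp <- pmin(m$nx, ix + 1L)
  iym <- pmax(1L, iy - 1L); iyp <- pmin(m$ny, iy + 1L)
  v <- fields$v
  gx <- (v[cbind(ixp, iy)] - v[cbind(ixm, iy)]) / ((ixp - ixm) * m$dx)
  gy <- (v[cbind(ix, iyp)] - v[cbind(ix, iym)]) / ((iyp - iym) * m$dx)
  cbind(gx, gy)
}

#' Calibrate the bound-VEGF threshold
#'
#' Computes the equilibrium bound-VEGF concentration on endothelium at a
#' given distance from the edge of an isolated hypoxic focus (a disk of
#' radius `focus_radius`): the VEGF field is integrated to steady state and
#' the bound fraction follows the VEGFR-2 binding isotherm
#' `e_0 * v / (v + k_m0/k_0)`. The default distance of twice the oxygen
#' diffusion length defines the reach over which a nascent hypoxic region
#' recruits and protects vessels. The package default `rv_crit` is this
#' value rounded to two significant digits.
#'
#' @param params a `pde_params`.
#' @param h0 hypoxic-cell concentration scale (uM).
#' @param distance distance from the focus edge (um).
#' @param focus_radius radius of the hypoxic disk (mm).
#' @param dx mesh spacing (mm).
#' @param domain_size side of the square calibration domain (mm).
#' @param max_days integration cap.
#' @param tol relative steady-state tolerance per day.
#' @export
calibrate_rv_crit <- function(params = pde_params(), h0 = 1e-2,
                              distance = 500, focus_radius = 0.25,
                              dx = 0.05, domain_size = 6, max_days = 150,
                              tol = 1e-8) {
  f <- calibration_fields(params, h0, focus_radius, dx, domain_size,
                          max_days, tol, "v")
  i <- mesh_index(f$mesh, domain_size / 2 + focus_radius + distance / 1000,
                  domain_size / 2)
  v_at <- f$v[i]
  kd <- params$k_m0 / params$k_0
  params$e_0 * v_at / (v_at + kd)
}

#' Calibrate the absolute bound-Ang-2 destabilization floor
#'
#' Equilibrium bound Ang-2 on endothelium at a given distance from the edge
#' of an isolated hypoxic focus, computed like [calibrate_rv_crit()] but
#' for the Ang-2 field and the Tie-2 binding isotherm (with no competing
#' Ang-1). Matching the rescue reach of `rv_crit`, hypoxia destabilizes the
#' vessels it cannot protect once VEGF signalling is suppressed. The
#' package default `ra2_floor` is this value rounded to two significant
#' digits.
#'
#' @inheritParams calibrate_rv_crit
#' @export
calibrate_ang2_floor <- function(params = pde_params(), h0 = 1e-2,
                                 distance = 500, focus_radius = 0.25,
                                 dx = 0.05, domain_size = 6, max_days = 150,
                                 tol = 1e-8) {
  f <- calibration_fields(params, h0, focus_radius, dx, domain_size,
                          max_days, tol, "a2")
  i <- mesh_index(f$mesh, domain_size / 2 + focus_radius + distance / 1000,
                  domain_size / 2)
  q <- params$k_2 * f$a2[i] / params$k_m2
  params$e_0 * q / (1 + q)
}

# steady ligand fields of a central hypoxic disk, no receptors
calibration_fields <- function(params, h0, focus_radius, dx, domain_size,
                               max_days, tol, watch) {
  mesh <- make_mesh(c(domain_size, domain_size), dx = dx)
  xc <- matrix(rep(mesh_xc(mesh), mesh$ny), mesh$nx, mesh$ny)
  yc <- matrix(rep(mesh_yc(mesh), each = mesh$nx), mesh$nx, mesh$ny)
  rr <- sqrt((xc - domain_size / 2)^2 + (yc - domain_size / 2)^2)
  zero <- matrix(0, mesh$nx, mesh$ny)
  ind <- structure(list(e = zero, h = (rr <= focus_radius) * 1,
                        p = zero, n = zero, h0 = h0, mesh = mesh,
                        map = NULL),
                   class = "indicator_raster")
  f <- init_field_state(mesh, NULL, params)
  for (d in seq_len(max_days)) {
    old <- f[[watch]]
    f <- step_fields_day(f, ind, params)
    if (max(abs(f[[watch]] - old)) <= tol * max(f[[watch]])) break
  }
  f$mesh <- mesh
  f
}
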