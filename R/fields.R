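#' Reaction-diffusion parameters for the VEGF/angiopoietin system
#'
#' Defaults are the model's standard values: diffusion in mm^2/h, rates in
#' 1/h, association constants in 1/(uM h), concentrations in uM. VEGF (`v`)
#' and Ang-2 (`a2`) diffuse; Ang-1 acts locally on the endothelium that
#' secretes it and does not diffuse; receptor species are bound to vessel
#' sites. `e_0` is the endothelial (receptor) concentration contributed by a
#' blood vessel at a grid site.
#'
#' @param D_v,D_a2 diffusion coefficients of VEGF and Ang-2 (mm^2/h).
#' @param b_v VEGF production rate by hypoxic cells (1/h).
#' @param b_a1,b_a2 Ang-1/Ang-2 production rates by ECs in malignant tissue
#'   (1/h).
#' @param bbar_a2 Ang-2 production rate by hypoxic cells (1/h).
#' @param mu_v,mu_a1,mu_a2 ligand decay rates (1/h).
#' @param k_0,k_m0 VEGF/VEGFR-2 association (1/(uM h)) and dissociation
#'   (1/h) rates.
#' @param k_1,k_m1 Ang-1/Tie-2 association and dissociation rates.
#' @param k_2,k_m2 Ang-2/Tie-2 association and dissociation rates.
#' @param K_v,K_a carrying capacities of VEGF and of the angiopoietins (uM).
#' @param e_0 endothelial cell concentration per blood vessel (uM).
#' @export
pde_params <- function(D_v = 3.6e-4, D_a2 = 3.6e-4,
                       b_v = 0.05, b_a1 = 0.01, b_a2 = 0.08, bbar_a2 = 0.05,
                       mu_v = 0.001, mu_a1 = 0.003, mu_a2 = 0.002,
                       k_0 = 46.8, k_m0 = 0.2268,
                       k_1 = 36, k_m1 = 0.1332,
                       k_2 = 41.7, k_m2 = 0.108,
                       K_v = 1e-2, K_a = 1.5e-2, e_0 = 1e-4) {
  p <- list(D_v = D_v, D_a2 = D_a2, b_v = b_v, b_a1 = b_a1, b_a2 = b_a2,
            bbar_a2 = bbar_a2, mu_v = mu_v, mu_a1 = mu_a1, mu_a2 = mu_a2,
            k_0 = k_0, k_m0 = k_m0, k_1 = k_1, k_m1 = k_m1, k_2 = k_2,
            k_m2 = k_m2, K_v = K_v, K_a = K_a, e_0 = e_0)
  if (any(vapply(p, function(z) !is.finite(z) || z < 0, logical(1)))) {
    stop("invalid argument: PDE parameters must be finite and non-negative")
  }
  structure(p, class = "pde_params")
}

#' Regular field mesh over the tissue domain
#'
#' @param domain numeric length-2 width/height in mm (or an
#'   `automaton_lattice`, whose domain is used).
#' @param dx grid spacing in mm; must lie in `[0.01, 0.5]` (10-500 um): finer
#'   meshes are pointless below the automaton cell size and coarser ones
#'   cannot resolve the 250 um diffusion length.
#' @export
make_mesh <- function(domain, dx = 0.1) {
  if (inherits(domain, "automaton_lattice")) domain <- domain$domain
  if (!is.finite(dx) || dx < 0.01 || dx > 0.5) {
    stop("invalid argument: mesh spacing dx must be between 0.01 and 0.5 mm")
  }
  nx <- max(3L, as.integer(ceiling(domain[[1]] / dx - 1e-9)))
  ny <- max(3L, as.integer(ceiling(domain[[2]] / dx - 1e-9)))
  structure(list(nx = nx, ny = ny, dx = dx,
                 width = domain[[1]], height = domain[[2]]),
            class = "field_mesh")
}

mesh_xc <- function(mesh) (seq_len(mesh$nx) - 0.5) * mesh$dx
mesh_yc <- function(mesh) (seq_len(mesh$ny) - 0.5) * mesh$dx

# linear (1-based) pixel index of points, clamped into the mesh
mesh_index <- function(mesh, x, y) {
  ix <- pmin(mesh$nx, pmax(1L, as.integer(floor(x / mesh$dx)) + 1L))
  iy <- pmin(mesh$ny, pmax(1L, as.integer(floor(y / mesh$dx)) + 1L))
  ix + (iy - 1L) * mesh$nx
}

# pixel->automaton-cell map: each pixel takes the cell whose (Voronoi)
# region contains its center, i.e. the nearest generator
mesh_cell_map <- function(mesh, lattice) {
  g <- expand.grid(x = mesh_xc(mesh), y = mesh_yc(mesh))
  nearest_center_cpp(g$x, g$y, lattice$centers[, 1], lattice$centers[, 2],
                     0, lattice$domain[["width"]],
                     0, lattice$domain[["height"]])
}

# linear pixel indices swept by each segment, sampled at dx/2 steps;
# returns a list of integer vectors (duplicates allowed -- callers use
# multiset counts, which stay consistent between add and remove)
segment_pixels <- function(mesh, ax, ay, bx, by) {
  n <- length(ax)
  out <- vector("list", n)
  if (n == 0L) return(out)
  len <- sqrt((bx - ax)^2 + (by - ay)^2)
  ns <- pmax(2L, as.integer(ceiling(len / (mesh$dx / 2))) + 1L)
  for (j in seq_len(n)) {
    tt <- seq(0, 1, length.out = ns[j])
    out[[j]] <- mesh_index(mesh, ax[j] + tt * (bx[j] - ax[j]),
                           ay[j] + tt * (by[j] - ay[j]))
  }
  out
}

#' Rasterize cell states and vasculature onto the field mesh
#'
#' Builds the indicator rasters entering the reaction-diffusion source
#' terms: `e` marks grid sites holding an alive vessel sub-segment, `h`,
#' `p`, `n` mark sites lying in hypoxic, proliferative and necrotic
#' automaton cells (mutually exclusive), and the hypoxic-cell concentration
#' field is `h0 * h`. ECs associated with malignant tissue enter the source
#' terms as the product `e * (p + h + n)`.
#'
#' @param lattice an `automaton_lattice`.
#' @param tumor a `tumor_state`.
#' @param network a `vessel_network`.
#' @param mesh a `field_mesh` (see [make_mesh()] for the resolution guard).
#' @param h0 hypoxic-cell concentration scale (uM).
#' @return an `indicator_raster`: matrices `e`, `h`, `p`, `n` (0/1) plus the
#'   mesh, the pixel-to-cell map and `h0`.
#' @export
rasterize_indicators <- function(lattice, tumor, network, mesh, h0 = 1e-2) {
  stopifnot(inherits(mesh, "field_mesh"))
  map <- mesh_cell_map(mesh, lattice)
  st <- tumor$states[map]
  np <- mesh$nx * mesh$ny
  e <- integer(np)
  al <- which(network$alive)
  if (length(al) > 0L) {
    pix <- segment_pixels(mesh, network$ax[al], network$ay[al],
                          network$bx[al], network$by[al])
    e[unique(unlist(pix, use.names = FALSE))] <- 1L
  }
  as_m <- function(v) matrix(as.numeric(v), mesh$nx, mesh$ny)
  structure(list(e = as_m(e),
                 h = as_m(st == STATE_HYPOXIC),
                 p = as_m(st == STATE_PROLIFERATIVE),
                 n = as_m(st == STATE_NECROTIC),
                 a = as_m(st == STATE_APOPTOTIC),
                 h0 = h0, mesh = mesh, map = map),
            class = "indicator_raster")
}

#' Initialize the eight concentration fields
#'
#' All ligand and complex fields start at zero. Unbound receptor fields
#' (`rv0` for VEGFR-2, `ra0` for Tie-2) are set to `e_0` at grid sites
#' holding a vessel if an indicator raster is supplied: receptors exist only
#' on the endothelium, and the system has no receptor production term, so
#' receptor totals are managed by vessel birth/death events.
#'
#' @param mesh a `field_mesh`.
#' @param indicators optional `indicator_raster` providing the vessel sites.
#' @param params a `pde_params` (for `e_0`).
#' @export
init_field_state <- function(mesh, indicators = NULL, params = pde_params()) {
  z <- matrix(0, mesh$nx, mesh$ny)
  f <- list(v = z, a1 = z, a2 = z, rv0 = z, ra0 = z, rv = z, ra1 = z, ra2 = z,
            mesh = mesh)
  if (!is.null(indicators)) {
    f$rv0 <- params$e_0 * indicators$e
    f$ra0 <- params$e_0 * indicators$e
  }
  structure(f, class = "field_state")
}

#' Integrate the reaction-diffusion system one day forward
#'
#' Explicit finite differences (five-point Laplacian for the two diffusing
#' ligands, zero-flux boundaries) with simultaneous sub-step updates; the
#' sub-step obeys both the diffusive CFL limit and half the inverse of the
#' largest linear reaction rate, which also preserves non-negativity.
#' Receptor totals `rv0 + rv` and `ra0 + ra1 + ra2` are conserved pointwise.
#'
#' @param fields a `field_state`.
#' @param indicators an `indicator_raster` on the same mesh.
#' @param params a `pde_params`.
#' @param hours integration horizon (h); one automaton step is 24 h.
#' @export
step_fields_day <- function(fields, indicators, params = pde_params(),
                            hours = 24) {
  m <- fields$mesh
  if (!identical(c(m$nx, m$ny), c(indicators$mesh$nx, indicators$mesh$ny))) {
    stop("invalid argument: fields and indicators use different meshes")
  }
  out <- pde_step_day_cpp(fields$v, fields$a1, fields$a2, fields$rv0,
                          fields$ra0, fields$rv, fields$ra1, fields$ra2,
                          as.numeric(indicators$e), as.numeric(indicators$h),
                          as.numeric(indicators$p), as.numeric(indicators$n),
                          indicators$h0, params, m$dx, hours)
  for (nm in c("v", "a1", "a2", "rv0", "ra0", "rv", "ra1", "ra2")) {
    fields[[nm]] <- out[[nm]]
  }
  attr(fields, "nsub") <- out$nsub
  attr(fields, "dt") <- out$dt
  fields
}

#' Bound-complex concentrations at a point
#'
#' Returns bound VEGF (`rv`), bound Ang-1 (`ra1`) and bound Ang-2 (`ra2`) at
#' the grid site containing `point` -- the three quantities the vessel
#' regression and sprouting rules read.
#'
#' @param fields a `field_state`.
#' @param point numeric length-2 coordinate in mm.
#' @export
bound_concentrations_at <- function(fields, point) {
  m <- fields$mesh
  if (point[1] < 0 || point[1] > m$nx * m$dx ||
      point[2] < 0 || point[2] > m$ny * m$dx) {
    stop("invalid argument: point lies outside the field mesh")
  }
  i <- mesh_index(m, point[1], point[2])
  c(rv = fields$rv[i], ra1 = fields$ra1[i], ra2 = fields$ra2[i])
}
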