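# cell-state codes; the palette convention is white / green / blue /
# yellow / black in this order
STATE_VIABLE <- 1L        # viable nonmalignant
STATE_APOPTOTIC <- 2L     # nonmalignant, dead by oxygen starvation
STATE_PROLIFERATIVE <- 3L
STATE_HYPOXIC <- 4L
STATE_NECROTIC <- 5L
STATE_NAMES <- c("viable", "apoptotic", "proliferative", "hypoxic",
                 "necrotic")
TUMOR_STATES <- c(STATE_PROLIFERATIVE, STATE_HYPOXIC, STATE_NECROTIC)

#' Growth-rule parameters
#'
#' @param p_min,p_max daily division probability at the edge of the
#'   vascularized band (`d_vessel = l_prolif`) and directly at a vessel.
#'   The defaults 0.1 and 0.284 correspond to cell doubling times of about
#'   seven and three days; their midpoint 0.192 to about four days.
#' @param l_prolif oxygen diffusion length (um): cells farther than this
#'   from a vessel are starved.
#' @param l_hyp hypoxic survival distance (um): hypoxic cells farther than
#'   this from a vessel become necrotic.
#' @param R_max maximum tumour extent (mm) imposed by mechanical
#'   confinement; the division probability falls linearly to zero there.
#' @export
growth_params <- function(p_min = 0.1, p_max = 0.284, l_prolif = 250,
                          l_hyp = 1500, R_max = 10) {
  if (!(p_min > 0 && p_max > p_min && p_max < 1)) {
    stop("invalid argument: need 0 < p_min < p_max < 1")
  }
  if (!(l_prolif > 0 && l_hyp > l_prolif)) {
    stop("invalid argument: need 0 < l_prolif < l_hyp")
  }
  if (!(R_max > 0)) stop("invalid argument: R_max must be positive")
  structure(list(p_min = p_min, p_max = p_max, l_prolif = l_prolif,
                 l_hyp = l_hyp, R_max = R_max), class = "growth_params")
}

#' Initialize the tumour state
#'
#' All cells start viable nonmalignant except the automaton cell containing
#' `seed_center` (the domain center by default), which is designated a
#' proliferative cancer cell.
#'
#' @param lattice an `automaton_lattice`.
#' @param seed_center numeric length-2 coordinate in mm, or NULL for the
#'   domain center.
#' @export
init_tumor_state <- function(lattice, seed_center = NULL) {
  if (is.null(seed_center)) {
    seed_center <- c(lattice$domain[["width"]] / 2,
                     lattice$domain[["height"]] / 2)
  }
  cell <- nearest_center_cpp(seed_center[1], seed_center[2],
                             lattice$centers[, 1], lattice$centers[, 2],
                             0, lattice$domain[["width"]],
                             0, lattice$domain[["height"]])
  states <- rep.int(STATE_VIABLE, lattice$n)
  states[cell] <- STATE_PROLIFERATIVE
  structure(list(states = states,
                 seed_cell = as.integer(cell),
                 seed_center = lattice$centers[cell, ],
                 day = 0L),
            class = "tumor_state")
}

#' Base division probability from vessel distance
#'
#' Linear interpolation between `p_max` at a vessel and `p_min` at the
#' oxygen diffusion length:
#' `p0 = (p_min - p_max)/l_prolif * d_vessel + p_max`. Only well-oxygenated
#' cells divide, so `d_vessel` must not exceed `l_prolif`.
#'
#' @param d_vessel distance to the nearest vessel, um (vectorised).
#' @param params a `growth_params`.
#' @export
base_division_probability <- function(d_vessel, params = growth_params()) {
  if (any(!is.finite(d_vessel)) || any(d_vessel < 0) ||
      any(d_vessel > params$l_prolif)) {
    stop(paste0("invalid argument: d_vessel must lie in [0, l_prolif]; a ",
                "cell farther from a vessel is hypoxic, not dividing"))
  }
  (params$p_min - params$p_max) / params$l_prolif * d_vessel + params$p_max
}

#' Division probability under mechanical confinement
#'
#' `p_div = p0 (1 - r / R_max)`, clamped at zero for `r >= R_max`: pressure
#' from the skull suppresses division linearly with distance from the
#' tumour center.
#'
#' @param p0 base division probability (per day), in (0, 1).
#' @param r distance from the tumour seed center, mm (vectorised).
#' @param params a `growth_params`.
#' @export
division_probability <- function(p0, r, params = growth_params()) {
  if (any(p0 <= 0) || any(p0 >= 1)) {
    stop("invalid argument: p0 must lie in (0, 1)")
  }
  if (any(r < 0)) stop("invalid argument: r must be non-negative")
  pmax(0, p0 * (1 - r / params$R_max))
}

#' Population doubling time of a daily division probability
#'
#' A population multiplying by `(1 + p)` per day doubles in
#' `log(2) / log(1 + p)` days; p = 0.192 gives about four days, and the
#' default `[p_min, p_max]` range spans roughly seven to three days.
#'
#' @param p daily division probability in (0, 1) (vectorised).
#' @return doubling time in days.
#' @export
expected_doubling_time <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("invalid argument: p must lie in (0, 1)")
  }
  log(2) / log(1 + p)
}

#' One day of cell-state transitions and stochastic division
#'
#' Applies, in order: (a) viable nonmalignant cells farther than `l_prolif`
#' from an alive vessel undergo apoptosis; (b) hypoxic cells within
#' `l_prolif` turn proliferative; (c) hypoxic cells farther than `l_hyp`
#' turn necrotic; (d) proliferative cells farther than `l_prolif` turn
#' hypoxic; then (e) each remaining proliferative cell attempts one
#' Bernoulli division with probability `p_div` from
#' [base_division_probability()] and [division_probability()], with `r`
#' measured from the seed center. A daughter occupies the dividing cell's
#' nearest neighbour; if that site already holds a tumour cell, the cell
#' labels are pushed outward along the shortest adjacency path through the
#' tumour to the nearest non-tumour cell, so one new proliferative cell
#' appears at the tumour periphery and the mass stays compact. A push that
#' finds no free cell (tumour filling the domain) annihilates with a
#' warning. Division order is reshuffled daily from `rng`. Necrotic cells
#' are inert and apoptotic sites may be re-occupied by pushed tumour cells.
#'
#' @param tumor a `tumor_state`.
#' @param lattice an `automaton_lattice`.
#' @param network a `vessel_network` (provides per-cell vessel distances).
#' @param rng an [rng_stream()].
#' @param params a `growth_params`.
#' @return the updated `tumor_state` (day advanced by one).
#' @export
update_cell_states <- function(tumor, lattice, network, rng,
                               params = growth_params()) {
  st <- tumor$states
  d_um <- network$cell_dist * 1000
  lp <- params$l_prolif
  lh <- params$l_hyp

  starved <- d_um > lp
  st[st == STATE_VIABLE & starved] <- STATE_APOPTOTIC
  hyp <- st == STATE_HYPOXIC
  st[hyp & !starved] <- STATE_PROLIFERATIVE
  st[hyp & d_um > lh] <- STATE_NECROTIC
  st[st == STATE_PROLIFERATIVE & starved] <- STATE_HYPOXIC

  prolif <- which(st == STATE_PROLIFERATIVE)
  lost <- 0L
  if (length(prolif) > 0L) {
    cx <- lattice$centers[, 1]
    cy <- lattice$centers[, 2]
    sx <- tumor$seed_center[[1]]
    sy <- tumor$seed_center[[2]]
    ord_u <- rng_draw(rng, function() {
      list(ord = sample.int(length(prolif)), u = runif(length(prolif)))
    })
    prolif <- prolif[ord_u$ord]
    p0 <- base_division_probability(pmin(d_um[prolif], lp), params)
    r <- sqrt((cx[prolif] - sx)^2 + (cy[prolif] - sy)^2)
    pdiv <- pmax(0, p0 * (1 - r / params$R_max))
    divide <- prolif[ord_u$u < pdiv]

    nearest <- lattice$nearest_neighbor
    nearest[is.na(nearest)] <- 0L
    dres <- divide_cells_cpp(lattice$adj_ptr, lattice$adj_idx, st, divide,
                             nearest)
    st <- dres$states
    lost <- dres$lost
  }
  if (lost > 0L) {
    warning(sprintf("%d outward push(es) annihilated at the domain boundary",
                    lost))
  }
  tumor$states <- st
  tumor$day <- tumor$day + 1L
  tumor
}

#' Effective tumour radius
#'
#' `sqrt(area / pi)` of the total tumour area (proliferative + hypoxic +
#' necrotic cell areas), in mm. Treatment protocols trigger on this radius.
#'
#' @param tumor a `tumor_state`.
#' @param lattice an `automaton_lattice`.
#' @export
tumor_radius <- function(tumor, lattice) {
  a <- sum(lattice$areas[tumor$states %in% TUMOR_STATES])
  if (a == 0) stop("invalid state: no tumour cells present")
  sqrt(a / pi)
}

#' @export
as.data.frame.tumor_state <- function(x, ...) {
  data.frame(id = seq_along(x$states), state = STATE_NAMES[x$states],
             stringsAsFactors = FALSE)
}

#' @export
print.tumor_state <- function(x, ...) {
  tab <- table(factor(STATE_NAMES[x$states], levels = STATE_NAMES))
  cat(sprintf("tumor state, day %d: %s\n", x$day,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
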