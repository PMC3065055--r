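derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1103 * k) %% 2147483647)
}

#' Simulation configuration
#'
#' Bundles every parameter of a run. Defaults are the model's standard
#' study conditions: a 20 x 20 mm tissue domain (accommodating the 10 mm
#' maximum tumour radius), ~106 um automaton cells, a 100 um field mesh,
#' and the Table-of-parameters defaults in [pde_params()],
#' [growth_params()], [vessel_placement_params()] and
#' [angiogenesis_params()].
#'
#' @param seed integer seed; every stochastic component derives its own
#'   stream from it.
#' @param domain width/height of the tissue domain in mm.
#' @param target_cell_diameter automaton cell diameter target (um).
#' @param rsa_factor hard-disk diameter as a fraction of the cell diameter.
#' @param dx field mesh spacing (mm).
#' @param h0 hypoxic-cell concentration scale (uM).
#' @param total_days number of simulated days.
#' @param snapshot_days days at which to store a state snapshot.
#' @param vessel,pde,growth,angio module parameter objects.
#' @param protocol a [treatment_protocol()] or `NULL` for untreated growth.
#' @param sprouting enable angiogenic sprouting.
#' @param angiogenic_response master switch for the endothelial VEGF
#'   response; `FALSE` disables both sprouting and VEGF rescue of
#'   destabilized vessels, modelling a tumour that cannot initiate
#'   angiogenesis at all.
#' @param verbose print a one-line summary every 30 days.
#' @export
simulation_config <- function(seed = 1L,
                              domain = c(20, 20),
                              target_cell_diameter = 105.9,
                              rsa_factor = 0.8,
                              dx = 0.1,
                              h0 = 1e-2,
                              total_days = 365L,
                              snapshot_days = integer(0),
                              vessel = vessel_placement_params(),
                              pde = pde_params(),
                              growth = growth_params(),
                              angio = angiogenesis_params(),
                              protocol = NULL,
                              sprouting = TRUE,
                              angiogenic_response = TRUE,
                              verbose = FALSE) {
  if (total_days < 0) stop("invalid argument: total_days must be >= 0")
  if (!angiogenic_response) {
    sprouting <- FALSE
    angio$vegf_rescue <- FALSE
  }
  structure(list(seed = as.integer(seed), domain = domain,
                 target_cell_diameter = target_cell_diameter,
                 rsa_factor = rsa_factor, dx = dx, h0 = h0,
                 total_days = as.integer(total_days),
                 snapshot_days = as.integer(snapshot_days),
                 vessel = vessel, pde = pde, growth = growth, angio = angio,
                 protocol = protocol, sprouting = sprouting,
                 angiogenic_response = angiogenic_response,
                 verbose = verbose),
            class = "simulation_config")
}

#' Load a simulation configuration from a YAML document
#'
#' Top-level keys are [simulation_config()] arguments; the nested sections
#' `vessel`, `pde`, `growth`, `angio` and `protocol` are passed to the
#' corresponding parameter constructors, so every model constant is a named
#' key with the standard default.
#'
#' @param path path to a YAML file.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  args <- y[setdiff(names(y), c("vessel", "pde", "growth", "angio",
                                "protocol"))]
  if (!is.null(y$vessel)) args$vessel <- build(vessel_placement_params, y$vessel)
  if (!is.null(y$pde)) args$pde <- build(pde_params, y$pde)
  if (!is.null(y$growth)) args$growth <- build(growth_params, y$growth)
  if (!is.null(y$angio)) args$angio <- build(angiogenesis_params, y$angio)
  if (!is.null(y$protocol)) args$protocol <- build(treatment_protocol, y$protocol)
  do.call(simulation_config, args)
}

#' Run one simulation
#'
#' Executes the daily loop in the fixed order: solve the reaction-diffusion
#' system one day forward, evolve the vasculature (regression, then
#' sprouting), update cell states (including stochastic division), then
#' apply treatment if a protocol is active. Treatment triggers on the first
#' day the effective tumour radius reaches the protocol's trigger radius;
#' the cytotoxic agent then acts daily through its window, the VDA on every
#' `vda_interval`-th day, and the AI as a sustained parameter change from
#' the day after the trigger until its configured duration ends.
#'
#' @param config a `simulation_config`.
#' @return a `simulation_result`: per-day `metrics` data frame, the final
#'   `lattice`, `network`, `tumor` and `fields`, the `trigger_day` (NA if
#'   never triggered) and any requested `snapshots`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  lattice <- generate_lattice(config$domain, config$target_cell_diameter,
                              seed = derive_seed(config$seed, 1),
                              rsa_factor = config$rsa_factor)
  network <- generate_native_network(lattice, config$vessel,
                                     seed = derive_seed(config$seed, 2))
  tumor <- init_tumor_state(lattice)
  rng_cells <- rng_stream(derive_seed(config$seed, 3))
  rng_treat <- rng_stream(derive_seed(config$seed, 4))
  rng_angio <- rng_stream(derive_seed(config$seed, 5))

  mesh <- make_mesh(lattice, config$dx)
  map <- mesh_cell_map(mesh, lattice)
  np <- mesh$nx * mesh$ny

  # multiset of alive sub-segments per pixel; e_i = (count > 0)
  pixlist <- vector("list", network$n)
  ecount <- integer(np)
  al0 <- which(network$alive)
  pixlist[al0] <- segment_pixels(mesh, network$ax[al0], network$ay[al0],
                                 network$bx[al0], network$by[al0])
  for (id in al0) ecount[pixlist[[id]]] <- ecount[pixlist[[id]]] + 1L

  e_now <- as.numeric(ecount > 0L)
  ind0 <- make_indicators(mesh, map, tumor$states, e_now, config$h0)
  fields <- init_field_state(mesh, ind0, config$pde)
  e_prev <- e_now

  proto <- config$protocol
  triggered <- FALSE
  trigger_day <- NA_integer_
  metrics <- vector("list", config$total_days + 1L)
  metrics[[1]] <- metrics_row(0L, tumor, lattice, network, 0L, 0L, 0L, 0L,
                              FALSE)
  snapshots <- list()

  for (day in seq_len(config$total_days)) {
    ind <- make_indicators(mesh, map, tumor$states, as.numeric(ecount > 0L),
                           config$h0)
    # receptors appear with vessel birth and vanish with vessel death
    born <- ind$e > 0 & e_prev == 0
    died <- ind$e == 0 & e_prev > 0
    if (any(born)) {
      fields$rv0[born] <- config$pde$e_0
      fields$rv[born] <- 0
      fields$ra0[born] <- config$pde$e_0
      fields$ra1[born] <- 0
      fields$ra2[born] <- 0
    }
    if (any(died)) {
      for (nm in c("rv0", "ra0", "rv", "ra1", "ra2")) fields[[nm]][died] <- 0
    }
    e_prev <- as.numeric(ind$e)

    ai_on <- !is.null(proto) && "AI" %in% proto$drugs && triggered &&
      (day - trigger_day) >= 1 && (day - trigger_day) <= proto$ai_duration
    if (ai_on) {
      eff <- apply_ai(config$pde, config$angio, proto)
    } else {
      eff <- list(pde = config$pde, angio = config$angio)
    }

    fields <- step_fields_day(fields, ind, eff$pde)

    reg <- regress_vessels(network, fields, ind, eff$angio, rng_angio)
    network <- reg$network
    for (id in reg$removed) ecount[pixlist[[id]]] <- ecount[pixlist[[id]]] - 1L

    n_sprout <- 0L
    if (config$sprouting) {
      spr <- sprout_vessels(network, fields, eff$angio, rng_angio, day)
      network <- spr$network
      if (spr$n_new > 0L) {
        newpix <- segment_pixels(mesh, network$ax[spr$new_ids],
                                 network$ay[spr$new_ids],
                                 network$bx[spr$new_ids],
                                 network$by[spr$new_ids])
        for (j in seq_along(spr$new_ids)) {
          pixlist[[spr$new_ids[j]]] <- newpix[[j]]
          ecount[newpix[[j]]] <- ecount[newpix[[j]]] + 1L
        }
      }
      n_sprout <- spr$n_new
    }

    tumor <- suppress_push_warnings(
      update_cell_states(tumor, lattice, network, rng_cells, config$growth))

    n_chemo <- 0L
    n_vda <- 0L
    if (!is.null(proto)) {
      if (!triggered &&
          tumor_radius_safe(tumor, lattice) >= proto$trigger_radius) {
        triggered <- TRUE
        trigger_day <- day
      }
      if (triggered) {
        since <- day - trigger_day
        if ("CYTOTOXIC" %in% proto$drugs && since < proto$cytotoxic_window) {
          ct <- apply_cytotoxic(tumor, proto, rng_treat, day)
          tumor <- ct$tumor
          n_chemo <- ct$n_killed
        }
        if ("VDA" %in% proto$drugs && since %% proto$vda_interval == 0 &&
            since < proto$vda_duration) {
          vd <- apply_vda(network, proto, rng_treat, day)
          network <- vd$network
          for (id in vd$removed) {
            ecount[pixlist[[id]]] <- ecount[pixlist[[id]]] - 1L
          }
          n_vda <- vd$n_removed
        }
      }
    }

    metrics[[day + 1L]] <- metrics_row(day, tumor, lattice, network,
                                       reg$n_removed, n_sprout, n_chemo,
                                       n_vda, triggered)
    if (day %in% config$snapshot_days) {
      snapshots[[as.character(day)]] <- list(day = day,
                                             states = tumor$states,
                                             alive = network$alive)
    }
    if (config$verbose && day %% 30L == 0L) {
      m <- metrics[[day + 1L]]
      cat(sprintf(
        "day %4d | tumor %7.2f mm^2 active %7.2f mm^2 r %5.2f mm | vessels %d+%d\n",
        day, m$tumor_area, m$active_area, m$radius, m$native_alive,
        m$angio_alive))
    }
  }

  structure(list(config = config,
                 metrics = do.call(rbind, metrics),
                 lattice = lattice, network = network, tumor = tumor,
                 fields = fields, trigger_day = trigger_day,
                 snapshots = snapshots),
            class = "simulation_result")
}

tumor_radius_safe <- function(tumor, lattice) {
  if (!any(tumor$states %in% TUMOR_STATES)) return(0)
  tumor_radius(tumor, lattice)
}

suppress_push_warnings <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("annihilated at the domain boundary", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

make_indicators <- function(mesh, map, states, e_vec, h0) {
  st <- states[map]
  as_m <- function(v) matrix(as.numeric(v), mesh$nx, mesh$ny)
  structure(list(e = as_m(e_vec),
                 h = as_m(st == STATE_HYPOXIC),
                 p = as_m(st == STATE_PROLIFERATIVE),
                 n = as_m(st == STATE_NECROTIC),
                 a = as_m(st == STATE_APOPTOTIC),
                 h0 = h0, mesh = mesh, map = map),
            class = "indicator_raster")
}

metrics_row <- function(day, tumor, lattice, network, n_regressed, n_sprouted,
                        n_chemo_killed, n_vda_removed, triggered) {
  st <- tumor$states
  counts <- tabulate(st, nbins = 5L)
  area_of <- function(k) sum(lattice$areas[st == k])
  tumor_area <- area_of(STATE_PROLIFERATIVE) + area_of(STATE_HYPOXIC) +
    area_of(STATE_NECROTIC)
  active_area <- area_of(STATE_PROLIFERATIVE) + area_of(STATE_HYPOXIC)
  data.frame(day = day,
             viable = counts[STATE_VIABLE],
             apoptotic = counts[STATE_APOPTOTIC],
             proliferative = counts[STATE_PROLIFERATIVE],
             hypoxic = counts[STATE_HYPOXIC],
             necrotic = counts[STATE_NECROTIC],
             tumor_area = tumor_area,
             active_area = active_area,
             radius = if (tumor_area > 0) sqrt(tumor_area / pi) else 0,
             native_alive = sum(network$alive & network$type == 1L),
             angio_alive = sum(network$alive & network$type == 2L),
             n_regressed = n_regressed,
             n_sprouted = n_sprouted,
             n_chemo_killed = n_chemo_killed,
             n_vda_removed = n_vda_removed,
             triggered = as.logical(triggered))
}

#' Run replicate simulations and average the metrics
#'
#' Runs `n` simulations with seeds `seed, seed + 1, ...` and reports the
#' per-day mean and standard deviation of every metric, the standard way
#' the model's average treatment response is reported (10 replicates).
#'
#' @param config a `simulation_config`.
#' @param n number of replicates.
#' @return a `replicate_summary`: data frames `mean` and `sd` plus the
#'   individual `runs` (metrics only).
#' @export
run_replicates <- function(config, n = 10) {
  stopifnot(n >= 1)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    runs[[i]] <- run_simulation(cfg)$metrics
  }
  num_cols <- names(runs[[1]])[vapply(runs[[1]], is.numeric, logical(1))]
  arr <- simplify2array(lapply(runs, function(m) as.matrix(m[, num_cols])))
  mu <- apply(arr, c(1, 2), mean)
  dev <- if (n > 1) apply(arr, c(1, 2), stats::sd) else arr[, , 1] * 0
  structure(list(mean = as.data.frame(mu), sd = as.data.frame(dev),
                 runs = runs, n = n, seed = config$seed),
            class = "replicate_summary")
}

#' Sensitivity sweep over a treatment parameter
#'
#' Runs one replicate batch per value of `T1`, `T2`, `T3` or `ai_mode` and
#' returns a long-format table of the per-day averaged metrics, one block
#' per parameter value.
#'
#' @param base a `simulation_config` with a non-NULL protocol.
#' @param parameter one of `"T1"`, `"T2"`, `"T3"`, `"ai_mode"`.
#' @param values vector of values to test.
#' @param n replicates per value.
#' @return list: `table` (long data frame) and `summaries` (one
#'   `replicate_summary` per value).
#' @export
sensitivity_sweep <- function(base, parameter, values, n = 10) {
  if (!parameter %in% c("T1", "T2", "T3", "ai_mode")) {
    stop("invalid argument: parameter must be one of T1, T2, T3, ai_mode")
  }
  if (is.null(base$protocol)) {
    stop("invalid argument: base config has no treatment protocol")
  }
  summaries <- list()
  tabs <- list()
  for (v in values) {
    cfg <- base
    cfg$protocol[[parameter]] <- v
    rs <- run_replicates(cfg, n)
    summaries[[as.character(v)]] <- rs
    tab <- rs$mean
    tab$active_area_sd <- rs$sd$active_area
    tab$tumor_area_sd <- rs$sd$tumor_area
    tab$parameter <- parameter
    tab$value <- as.character(v)
    tabs[[as.character(v)]] <- tab
  }
  list(table = do.call(rbind, tabs), summaries = summaries)
}

#' Render a snapshot image of the tissue
#'
#' Standard colour convention: viable nonmalignant cells white, apoptotic
#' nonmalignant cells green, proliferative tumour cells blue, hypoxic
#' tumour cells yellow, necrotic tumour cells black; native vessels red and
#' angiogenic vessels purple.
#'
#' @param tumor a `tumor_state`.
#' @param network a `vessel_network`.
#' @param lattice an `automaton_lattice`.
#' @param px_per_mm raster resolution.
#' @return an `ny x nx x 3` numeric array in `[0, 1]`, row 1 at the top of
#'   the domain; write it with [write_snapshot_png()].
#' @export
render_snapshot <- function(tumor, network, lattice, px_per_mm = 20) {
  w <- lattice$domain[["width"]]
  h <- lattice$domain[["height"]]
  nx <- max(1L, as.integer(round(w * px_per_mm)))
  ny <- max(1L, as.integer(round(h * px_per_mm)))
  xc <- (seq_len(nx) - 0.5) / px_per_mm
  yc <- (seq_len(ny) - 0.5) / px_per_mm
  g <- expand.grid(x = xc, y = yc)
  cellof <- nearest_center_cpp(g$x, g$y, lattice$centers[, 1],
                               lattice$centers[, 2], 0, w, 0, h)
  pal <- rbind(viable = c(1, 1, 1),
               apoptotic = c(0, 1, 0),
               proliferative = c(0, 0, 1),
               hypoxic = c(1, 1, 0),
               necrotic = c(0, 0, 0))
  rgbv <- pal[tumor$states[cellof], , drop = FALSE]
  red <- c(1, 0, 0)
  purple <- c(160, 32, 240) / 255
  px_of <- function(x, y) {
    ix <- pmin(nx, pmax(1L, as.integer(floor(x * px_per_mm)) + 1L))
    iy <- pmin(ny, pmax(1L, as.integer(floor(y * px_per_mm)) + 1L))
    ix + (iy - 1L) * nx
  }
  paint <- function(rgbv, ids, col) {
    if (length(ids) == 0L) return(rgbv)
    ax <- network$ax[ids]; ay <- network$ay[ids]
    bx <- network$bx[ids]; by <- network$by[ids]
    len <- sqrt((bx - ax)^2 + (by - ay)^2)
    ns <- pmax(2L, as.integer(ceiling(len * px_per_mm * 2)) + 1L)
    for (j in seq_along(ids)) {
      tt <- seq(0, 1, length.out = ns[j])
      p <- px_of(ax[j] + tt * (bx[j] - ax[j]), ay[j] + tt * (by[j] - ay[j]))
      rgbv[p, ] <- matrix(col, length(p), 3, byrow = TRUE)
    }
    rgbv
  }
  rgbv <- paint(rgbv, which(network$alive & network$type == 1L), red)
  rgbv <- paint(rgbv, which(network$alive & network$type == 2L), purple)
  img <- array(0, c(ny, nx, 3))
  for (k in 1:3) img[, , k] <- t(matrix(rgbv[, k], nx, ny))[ny:1, , drop = FALSE]
  attr(img, "palette") <- rbind(pal, native = red, angiogenic = purple)
  img
}

#' Reconstruct the stored state of a simulation day
#'
#' Returns `tumor` and `network` objects reflecting a snapshot day of a
#' finished run (segments born after that day are marked dead), ready for
#' [render_snapshot()].
#'
#' @param result a `simulation_result`.
#' @param day a day present in `config$snapshot_days`.
#' @export
snapshot_state <- function(result, day) {
  s <- result$snapshots[[as.character(day)]]
  if (is.null(s)) stop("invalid argument: no snapshot stored for that day")
  tumor <- result$tumor
  tumor$states <- s$states
  tumor$day <- s$day
  network <- result$network
  alive <- rep.int(FALSE, network$n)
  alive[seq_along(s$alive)] <- s$alive
  network$alive <- alive
  list(tumor = tumor, network = network)
}

#' Write a rendered snapshot to a PNG file
#' @param img array from [render_snapshot()].
#' @param path output file path.
#' @export
write_snapshot_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(paste0("simulation: %d days, tumor %.2f mm^2 (active %.2f), ",
                     "radius %.2f mm, trigger day %s\n"),
              m$day, m$tumor_area, m$active_area, m$radius,
              ifelse(is.na(x$trigger_day), "none", x$trigger_day)))
  invisible(x)
}
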