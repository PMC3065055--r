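# shared fixtures, built once per test session

.fixtures <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

small_lattice <- function() {
  fixture("lat2", function() generate_lattice(c(2, 2), seed = 42L))
}

small_network <- function() {
  fixture("net2", function() {
    suppressWarnings(generate_native_network(small_lattice(), seed = 7L))
  })
}

mid_lattice <- function() {
  fixture("lat3", function() generate_lattice(c(3, 3), seed = 11L))
}

mid_network <- function() {
  fixture("net3", function() {
    suppressWarnings(generate_native_network(mid_lattice(), seed = 5L))
  })
}

# a network with an angiogenic chain a1 -> a2 -> a3 hanging off the first
# native sub-segment, for cascade tests
chain_network <- function() {
  fixture("chain_net", function() {
    net <- small_network()
    s <- 0.1
    r1 <- vasctum:::append_segments(net, 0.5, 0.5, 0.5 + s, 0.5, 1L, 1, TRUE)
    r2 <- vasctum:::append_segments(r1$network, 0.5 + s, 0.5, 0.5 + 2 * s,
                                    0.5, r1$ids, 2, TRUE)
    r3 <- vasctum:::append_segments(r2$network, 0.5 + 2 * s, 0.5,
                                    0.5 + 3 * s, 0.5, r2$ids, 3, TRUE)
    list(network = r3$network, chain = c(r1$ids, r2$ids, r3$ids))
  })
}

# ray-casting point-in-polygon (strictly inside up to eps)
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xint <- poly[j, 1] + (py - poly[j, 2]) / (poly[i, 2] - poly[j, 2]) *
        (poly[i, 1] - poly[j, 1])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# independent flow-dependency closure: BFS over parent pointers
closure_oracle <- function(network, doomed) {
  out <- as.integer(doomed)
  repeat {
    kids <- which(network$alive & !is.na(network$parent) &
                    network$parent %in% out & !(seq_len(network$n) %in% out))
    if (length(kids) == 0L) break
    out <- c(out, kids)
  }
  sort(out)
}

# homogeneous-limit ODE right-hand side of the eight-species system, for
# use with deSolve as an independent oracle
homogeneous_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    mi <- pi_ind + hi + ni
    hconc <- h0 * hi
    bindv <- k_0 * v * rv0 - k_m0 * rv
    bind1 <- k_1 * a1 * ra0 - k_m1 * ra1
    bind2 <- k_2 * a2 * ra0 - k_m2 * ra2
    list(c(
      v = b_v * hi * (hconc - v^2 / K_v) - bindv - mu_v * v,
      a1 = b_a1 * ei * mi * (e_0 - a1^2 / K_a) - bind1 - mu_a1 * a1,
      a2 = b_a2 * ei * mi * (e_0 - a2^2 / K_a) +
        bbar_a2 * hi * (hconc - a2^2 / K_a) - bind2 - mu_a2 * a2,
      rv0 = -bindv, ra0 = -(bind1 + bind2),
      rv = bindv, ra1 = bind1, ra2 = bind2))
  })
}

run_homogeneous_oracle <- function(params, h0, ei, hi, pi_ind, ni, y0, days) {
  parms <- c(unclass(params), h0 = h0, ei = ei, hi = hi, pi_ind = pi_ind,
             ni = ni)
  out <- deSolve::ode(y = y0, times = c(0, days * 24), func = homogeneous_rhs,
                      parms = parms, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  out[nrow(out), -1]
}
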