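#' Mechanical and kinetic base parameters
#'
#' Bundles the thermal energy, pulling speed and Monte Carlo time step shared
#' by both filament simulators.  The default `kBT` of 4.114 pN nm corresponds
#' to room temperature (25 C); energies per length reported downstream use
#' this value to convert pN nm to kBT.
#'
#' @param kBT Thermal energy in pN nm.  Default 4.114 (25 C).
#' @param pulling_speed Speed of the distance ramp in nm/s.
#' @param dt Base Monte Carlo time step in s.  The steppers subdivide it
#'   automatically whenever a per-step transition probability would exceed
#'   `p_max`, so `dt` mainly sets the sampling density of the recorded trace.
#' @param p_max Upper bound enforced on any single-step transition
#'   probability (default 0.1).
#' @return An object of class `mechanical_params`.
#' @export
mechanical_params <- function(kBT = 4.114, pulling_speed = 500, dt = 2e-3,
                              p_max = 0.1) {
  if (kBT <= 0) stop("kBT must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (pulling_speed <= 0) stop("pulling_speed must be positive")
  if (p_max <= 0 || p_max >= 1) stop("p_max must lie in (0, 1)")
  structure(list(kBT = kBT, pulling_speed = pulling_speed, dt = dt,
                 p_max = p_max),
            class = "mechanical_params")
}

#' Bell rate for a force-activated transition
#'
#' Slip-bond kinetics: the transition rate grows exponentially with the
#' tension on the element, `k(F) = k0 * exp(F * x / kBT)`.
#'
#' @param F Tension on the element in pN (scalar or vector, >= 0).
#' @param k0 Zero-force rate in 1/s (>= 0).
#' @param x Distance to the transition state in nm (>= 0).
#' @param kBT Thermal energy in pN nm (> 0).
#' @return Rate(s) in 1/s.
#' @examples
#' bell_rate(0, k0 = 0.1, x = 0.5)        # zero-force limit: k0
#' bell_rate(4.114, k0 = 1, x = 1)        # exponent 1: exp(1)
#' @export
bell_rate <- function(F, k0, x, kBT = 4.114) {
  if (kBT <= 0) stop("kBT must be positive")
  if (any(F < 0)) stop("F must be non-negative")
  if (any(k0 < 0) || any(x < 0)) stop("k0 and x must be non-negative")
  k0 * exp(F * x / kBT)
}

#' Per-step transition probability from a rate
#'
#' Probability that at least one event of a Poisson process with the given
#' rate occurs within `dt`: `1 - exp(-rate * dt)`.
#'
#' @param rate Rate(s) in 1/s (>= 0).
#' @param dt Time step in s (> 0).
#' @return Probability in [0, 1).
#' @export
step_probability <- function(rate, dt) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  -expm1(-rate * dt)
}

#' Build a filament lattice of serial springs and lateral bonds
#'
#' Describes the discrete mechanical state used by [network_force()]: an
#' `n_serial x n_parallel` array of axial spring segments (one protofilament
#' per column) with lateral bonds coupling neighbouring protofilaments at
#' each internal node.  Open lateral bonds transmit no force; broken
#' longitudinal springs carry none either, so a cross-section in which every
#' protofilament is broken disconnects the network.
#'
#' @param n_serial Number of axial segments per protofilament (>= 2).
#' @param n_parallel Number of protofilaments (>= 2).
#' @param spring_k Longitudinal spring stiffness per segment, pN/nm.  Scalar
#'   or `n_serial x n_parallel` matrix.
#' @param rest Rest length per segment in nm (scalar or matrix).  Slipped
#'   segments carry a longer rest length.
#' @param bond_k Lateral bond stiffness, pN/nm (axial shear coupling).
#' @param bond_state Logical `n_serial - 1` + 1 ... matrix of dimension
#'   `(n_serial - 1) x (n_parallel - 1)` (internal nodes x neighbour pairs);
#'   `TRUE` = CLOSED.  Default all closed.
#' @param spring_ok Logical matrix like `spring_k`; `FALSE` marks a broken
#'   segment.  Default all intact.
#' @return An object of class `filament_lattice`.
#' @export
filament_lattice <- function(n_serial, n_parallel, spring_k, rest,
                             bond_k = 10,
                             bond_state = NULL, spring_ok = NULL) {
  if (n_serial < 2 || n_parallel < 2)
    stop("need n_serial >= 2 and n_parallel >= 2")
  as_mat <- function(x) matrix(x, n_serial, n_parallel)
  spring_k <- as_mat(spring_k)
  rest <- as_mat(rest)
  if (any(spring_k <= 0)) stop("spring stiffness must be positive")
  if (any(rest < 0)) stop("rest lengths must be non-negative")
  if (is.null(bond_state))
    bond_state <- matrix(TRUE, n_serial - 1L, n_parallel - 1L)
  if (is.null(spring_ok))
    spring_ok <- matrix(TRUE, n_serial, n_parallel)
  stopifnot(all(dim(bond_state) == c(n_serial - 1L, n_parallel - 1L)),
            all(dim(spring_ok) == c(n_serial, n_parallel)))
  structure(list(n_serial = n_serial, n_parallel = n_parallel,
                 spring_k = spring_k, rest = rest, bond_k = bond_k,
                 bond_state = bond_state, spring_ok = spring_ok),
            class = "filament_lattice")
}

#' Tension of a spring-and-bond lattice at an imposed end-to-end distance
#'
#' Solves the quasi-static force balance of the full node network: all
#' protofilament left ends are clamped at 0, all right ends at
#' `end_distance`, internal node positions equilibrate.  Longitudinal
#' springs act along the axis; closed lateral bonds penalise the axial
#' offset between neighbouring protofilaments at the same internal node.
#' Returns the total tension transmitted to the right clamp.
#'
#' If every protofilament is broken at some cross-section the two clamps are
#' mechanically disconnected: a condition of class `ifmech_rupture` is
#' signalled rather than a number.
#'
#' @param lattice A [filament_lattice()].
#' @param end_distance Imposed end-to-end distance in nm (>= 0).
#' @return Tension in pN.
#' @export
network_force <- function(lattice, end_distance) {
  stopifnot(inherits(lattice, "filament_lattice"))
  if (end_distance < 0) stop("end_distance must be non-negative")
  ns <- lattice$n_serial; np <- lattice$n_parallel
  # rupture: a cross-section i where no protofilament segment is intact
  if (any(rowSums(lattice$spring_ok) == 0))
    stop(structure(class = c("ifmech_rupture", "error", "condition"),
                   list(message = "network disconnected: full cross-section broken",
                        call = sys.call(-1))))
  # unknowns: internal nodes (i = 1..ns-1, j = 1..np), axial positions u_ij
  n_int <- (ns - 1L) * np
  idx <- function(i, j) (j - 1L) * (ns - 1L) + i
  trips_i <- integer(0); trips_j <- integer(0); trips_x <- numeric(0)
  b <- numeric(n_int)
  add <- function(i, j, v) {
    trips_i <<- c(trips_i, i); trips_j <<- c(trips_j, j); trips_x <<- c(trips_x, v)
  }
  for (j in seq_len(np)) {
    for (seg in seq_len(ns)) {
      k <- if (lattice$spring_ok[seg, j]) lattice$spring_k[seg, j] else 0
      r <- lattice$rest[seg, j]
      lo <- seg - 1L; hi <- seg  # nodes bounding the segment (0..ns)
      # spring force contributes k*(u_hi - u_lo - r); build Laplacian + rhs
      for (nd in c(lo, hi)) {
        if (nd == 0L || nd == ns) next
        sgn <- if (nd == hi) 1 else -1
        add(idx(nd, j), idx(nd, j), k)
        other <- if (nd == hi) lo else hi
        if (other != 0L && other != ns)
          add(idx(nd, j), idx(other, j), -k)
        # rhs pieces: clamped neighbours and rest lengths
        if (other == 0L) b[idx(nd, j)] <- b[idx(nd, j)] + 0
        if (other == ns) b[idx(nd, j)] <- b[idx(nd, j)] + k * end_distance
        b[idx(nd, j)] <- b[idx(nd, j)] + sgn * k * r
      }
    }
  }
  # lateral bonds at internal nodes i = 1..ns-1 between pf j and j+1
  for (j in seq_len(np - 1L)) {
    for (i in seq_len(ns - 1L)) {
      if (!lattice$bond_state[i, j]) next
      kb <- lattice$bond_k
      a <- idx(i, j); bb <- idx(i, j + 1L)
      add(a, a, kb); add(bb, bb, kb); add(a, bb, -kb); add(bb, a, -kb)
    }
  }
  A <- Matrix::sparseMatrix(i = trips_i, j = trips_j, x = trips_x,
                            dims = c(n_int, n_int))
  # isolated nodes (both adjoining springs broken, no closed lateral bond)
  dg <- Matrix::diag(A)
  free <- which(dg == 0)
  if (length(free)) {
    for (f in free) A[f, f] <- 1  # pin mechanically irrelevant nodes
  }
  u <- as.numeric(Matrix::solve(A, b))
  # total tension at the right clamp
  f_tot <- 0
  for (j in seq_len(np)) {
    if (!lattice$spring_ok[ns, j]) next
    u_prev <- if (ns - 1L >= 1L) u[idx(ns - 1L, j)] else 0
    f_tot <- f_tot +
      lattice$spring_k[ns, j] * (end_distance - u_prev - lattice$rest[ns, j])
  }
  f_tot
}

#' Number of substeps needed to respect the probability cap
#'
#' @param max_rate Largest eligible transition rate, 1/s.
#' @param dt Base step, s.
#' @param p_max Probability cap per substep.
#' @return Integer >= 1.
#' @keywords internal
n_substeps <- function(max_rate, dt, p_max = 0.1) {
  if (!is.finite(max_rate) || max_rate <= 0) return(1L)
  # p = 1 - exp(-r dt/n) < p_max  <=>  n > r dt / -log(1 - p_max)
  max(1L, ceiling(max_rate * dt / -log1p(-p_max)))
}
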