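# shared fixtures: small deterministic traces and reduced-size model runs

# exact linear force-distance trace F = k_d * (d - d0), one stretch branch
linear_stretch <- function(k_d = 0.5, d0 = 900, d = seq(880, 1500, by = 2),
                           cycle = 1) {
  data.frame(cycle = cycle, branch = "stretch",
             t_s = seq_along(d) * 1e-2, d_nm = d,
             F_pN = pmax(0, k_d * (d - d0)))
}

# full triangle cycle: linear stretch, relax at a force fraction
triangle_cycle <- function(k_d = 0.5, d0 = 900, d_max = 1500,
                           relax_fraction = 0.5, cycle = 1, n = 200) {
  d_up <- seq(d0 - 20, d_max, length.out = n)
  d_dn <- rev(d_up)
  f_up <- pmax(0, k_d * (d_up - d0))
  rbind(
    data.frame(cycle = cycle, branch = "stretch", t_s = seq_len(n) * 1e-2,
               d_nm = d_up, F_pN = f_up),
    data.frame(cycle = cycle, branch = "relax",
               t_s = (n + seq_len(n)) * 1e-2, d_nm = d_dn,
               F_pN = relax_fraction * pmax(0, k_d * (d_dn - d0))))
}

# small keratin configuration for fast kinetic tests
small_keratin <- function(...) keratin_params(n_serial = 6, n_parallel = 4,
                                              n_helix = 3, ...)

# dense independent assembly of the lattice force balance: build the node
# equilibrium equations with explicit loops and solve with base R
dense_network_force <- function(lattice, d) {
  ns <- lattice$n_serial; np <- lattice$n_parallel
  nid <- function(i, j) j + np * i  # i = 0..ns (axial), j = 1..np
  n_nodes <- np * (ns + 1)
  K <- matrix(0, n_nodes, n_nodes); f0 <- numeric(n_nodes)
  add_spring <- function(a, b, k, r) {
    # spring force k * (x_b - x_a - r)
    K[a, a] <<- K[a, a] + k; K[b, b] <<- K[b, b] + k
    K[a, b] <<- K[a, b] - k; K[b, a] <<- K[b, a] - k
    f0[a] <<- f0[a] + k * r; f0[b] <<- f0[b] - k * r
  }
  for (j in seq_len(np))
    for (i in seq_len(ns))
      if (lattice$spring_ok[i, j])
        add_spring(nid(i - 1, j), nid(i, j), lattice$spring_k[i, j],
                   lattice$rest[i, j])
  for (j in seq_len(np - 1))
    for (i in seq_len(ns - 1))
      if (lattice$bond_state[i, j])
        add_spring(nid(i, j), nid(i, j + 1), lattice$bond_k, 0)
  fixed0 <- vapply(seq_len(np), function(j) nid(0, j), 0)
  fixedd <- vapply(seq_len(np), function(j) nid(ns, j), 0)
  x <- numeric(n_nodes); x[fixedd] <- d
  free <- setdiff(seq_len(n_nodes), c(fixed0, fixedd))
  rhs <- -f0[free] - K[free, c(fixed0, fixedd), drop = FALSE] %*%
    x[c(fixed0, fixedd)]
  deg <- diag(K)[free]
  keep <- deg > 0
  x[free[keep]] <- solve(K[free[keep], free[keep], drop = FALSE],
                         rhs[keep, , drop = FALSE])
  # tension on the right clamp
  f_tot <- 0
  for (j in seq_len(np))
    if (lattice$spring_ok[ns, j])
      f_tot <- f_tot + lattice$spring_k[ns, j] *
        (d - x[nid(ns - 1, j)] - lattice$rest[ns, j])
  f_tot
}

random_lattice <- function(ns, np, p_open = 0.2, p_broken = 0.05) {
  repeat {
    spring_ok <- matrix(runif(ns * np) > p_broken, ns, np)
    if (all(rowSums(spring_ok) > 0)) break
  }
  filament_lattice(
    ns, np,
    spring_k = matrix(runif(ns * np, 0.5, 3), ns, np),
    rest = matrix(runif(ns * np, 20, 60), ns, np),
    bond_k = runif(1, 1, 20),
    bond_state = matrix(runif((ns - 1) * (np - 1)) > p_open, ns - 1, np - 1),
    spring_ok = spring_ok)
}
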