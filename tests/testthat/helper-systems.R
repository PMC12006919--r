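# small builders and numeric helpers shared across tests

toy_system <- function(coords, name = "CA", resname = "GLY",
                       chain = "A", ...) {
  coords <- matrix(coords, ncol = 3)
  particle_system(data.frame(
    name = name, resname = resname, resid = seq_len(nrow(coords)),
    chain = chain, x = coords[, 1], y = coords[, 2], z = coords[, 3], ...))
}

# central-difference gradient of a scalar energy function of coords
num_grad <- function(fn, coords, h = 1e-5) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) for (a in 1:3) {
    cp <- coords; cp[i, a] <- cp[i, a] + h
    cm <- coords; cm[i, a] <- cm[i, a] - h
    g[i, a] <- (fn(cp) - fn(cm)) / (2 * h)
  }
  g
}

# relative agreement between analytic forces and -numerical gradient
grad_rel_err <- function(fn, forces, coords, h = 1e-5) {
  ng <- num_grad(fn, coords, h)
  max(abs(forces + ng)) / max(abs(ng), 1e-12)
}

random_cloud <- function(n, box = 30) matrix(runif(3 * n, 0, box), n, 3)
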