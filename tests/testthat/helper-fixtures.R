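# Shared fixtures, generated in code.

fixture_system <- local({
  sys <- NULL
  function() {
    if (is.null(sys)) sys <<- build_synthetic_system()
    sys
  }
})

# brute-force minimum distance over the 27 neighbouring periodic images
brute_min_image <- function(p, q, box, span = 3) {
  L <- box$lengths
  shifts <- expand.grid(i = -span:span, j = -span:span, k = -span:span)
  shifts$i <- shifts$i * ifelse(box$periodic[1], L[1], 0)
  shifts$j <- shifts$j * ifelse(box$periodic[2], L[2], 0)
  shifts$k <- shifts$k * ifelse(box$periodic[3], L[3], 0)
  min(apply(shifts, 1, function(s) sqrt(sum((p - q + as.numeric(s))^2))))
}

# independent superposition oracle: coarse Euler-angle grid then simplex
# refinement of the RMSD objective, never touching the SVD path
euler_rot <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3)
  Rz %*% Ry %*% Rx
}

brute_force_rmsd <- function(ref, mov) {
  refc <- sweep(ref, 2, colMeans(ref))
  movc <- sweep(mov, 2, colMeans(mov))
  obj <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((movc %*% t(R) - refc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; bp <- NULL
  for (a in grid) for (b in seq(0, pi, length.out = 7)) for (cc in grid) {
    v <- obj(c(a, b, cc))
    if (v < best) { best <- v; bp <- c(a, b, cc) }
  }
  stats::optim(bp, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_traj <- function(coords_list, labels, times = NULL, box = NULL) {
  nf <- length(coords_list)
  np <- nrow(coords_list[[1]])
  co <- array(0, c(nf, np, 3))
  for (f in seq_len(nf)) co[f, , ] <- coords_list[[f]]
  trajectory(times %||% (seq_len(nf) - 1), co, labels, box = box)
}

# toy fixed-column PDB lines
toy_pdb_lines <- function() {
  c("ATOM      1  CZ  ARG A 397       1.000   2.000   3.000  1.00  0.00           C",
    "HETATM    2  CA  ASP L 500       4.000   5.000   6.000  1.00  0.00           C")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}
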