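# Shared fixtures: small bases, scenes and scenario settings built in code.

basis8 <- build_basis_2d(8)
basis16 <- build_basis_2d(16)
basis32 <- build_basis_2d(32)

bars32 <- render_bars(32, 3, 3)   # width-3 bars: sequency content beyond 20%
disc32 <- scene(render_pacman_video(32, n_frames = 2)$frames[[1]])

# A strongly rippling ambient source whose total collected flux exceeds the
# object flux (halogen lamp behaviour, 100 Hz).
strong_ripple <- function(p0 = 1) {
  illumination_model(p0 = p0, parasite_baseline = 1.0, ripple_amplitude = 0.8)
}

random_scene <- function(side, seed) {
  set.seed(seed)
  scene(matrix(runif(side^2), side, side))
}

# Dense matrices for the sensing operator and the TV gradient on an s x s
# grid, for oracle comparisons on tiny instances.
dense_operators <- function(basis, subset) {
  s <- basis$size
  N <- s^2
  Phi <- t(vapply(subset$indices, function(i) as.vector(basis_function(basis, i)),
                  numeric(N)))
  unit <- function(j) {
    e <- matrix(0, s, s); e[j] <- 1; e
  }
  Dh <- matrix(0, N, N); Dv <- matrix(0, N, N)
  for (j in seq_len(N)) {
    g <- balancedSPI:::tv_grad(unit(j))
    Dh[, j] <- as.vector(g$h)
    Dv[, j] <- as.vector(g$v)
  }
  list(Phi = Phi, Dh = Dh, Dv = Dv)
}

# Independent convex oracle: anisotropic TV minimization under equality
# constraints recast as a linear program and solved by a generic LP solver
# (scipy HiGHS), entirely outside the package's solver path.
tv_lp_oracle <- function(Phi, Dh, Dv, y) {
  payload <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(list(Phi = Phi, Dh = Dh, Dv = Dv, y = y),
                       payload, digits = NA, matrix = "rowmajor")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "Phi = np.array(d['Phi']); Dh = np.array(d['Dh']); Dv = np.array(d['Dv'])",
    "y = np.array(d['y'], dtype=float).ravel()",
    "N = Phi.shape[1]",
    "D = np.vstack([Dh, Dv]); K = D.shape[0]",
    "# variables: x (N), t (K); min sum(t) s.t. -t <= D x <= t, Phi x = y",
    "c = np.concatenate([np.zeros(N), np.ones(K)])",
    "A_ub = np.block([[D, -np.eye(K)], [-D, -np.eye(K)]])",
    "b_ub = np.zeros(2 * K)",
    "A_eq = np.hstack([Phi, np.zeros((Phi.shape[0], K))])",
    "res = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=y,",
    "              bounds=[(None, None)] * (N + K), method='highs')",
    "json.dump({'objective': res.fun, 'status': int(res.status)},",
    "          open(sys.argv[2], 'w'))"
  ), script)
  status <- system2("python", c(script, payload, outfile))
  expect_identical(status, 0L)
  res <- jsonlite::read_json(outfile)
  expect_identical(res$status, 0L)
  res$objective
}
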