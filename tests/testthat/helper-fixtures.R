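# shared small fixtures, built once per test run

path_graph <- function(n) {
  region_graph(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

sp_path3 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- scale_icar(path_graph(3))
    val
  }
})

sp_lattice3 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- scale_icar(build_lattice_graph(3, 3))
    val
  }
})

sp_lattice19 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- scale_icar(build_lattice_graph(19, 19))
    val
  }
})

# dense Moore-Penrose pseudo-inverse via eigendecomposition (oracle path,
# independent of the package's per-component scaling code)
dense_pinv <- function(A, tol = 1e-10) {
  eg <- eigen(as.matrix(A), symmetric = TRUE)
  pos <- abs(eg$values) > tol * max(abs(eg$values))
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

# trapezoid quadrature on a fixed grid (stable near the phi -> 1 endpoint
# where adaptive quadrature struggles with the interpolated density)
trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
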