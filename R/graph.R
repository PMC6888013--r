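#' Region adjacency graphs
#'
#' A `region_graph` is an undirected adjacency structure over `n` areal
#' units (counties, municipalities, lattice cells). It is the neighborhood
#' structure behind the intrinsic CAR precision matrix used by the spatial
#' models: two regions are neighbors when they share a border.
#'
#' @param n_regions number of regions (positive integer, at least 2 for any
#'   model use).
#' @param edges two-column integer matrix of region index pairs (1-based);
#'   each row is one undirected edge. Self-loops and duplicate edges are
#'   rejected.
#' @param labels optional character vector of region names.
#' @return An object of class `region_graph` with elements `n`, `edges`
#'   (canonicalized so the smaller index is first, rows sorted), and
#'   `labels`.
#' @examples
#' g <- region_graph(3, rbind(c(1, 2), c(2, 3)))
#' g$n
#' @export
region_graph <- function(n_regions, edges, labels = NULL) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 1 ||
      n_regions != round(n_regions))
    stopf("n_regions must be a positive integer")
  n <- as.integer(n_regions)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(edges < 1L | edges > n))
      stopf("edge indices must lie in [1, %d]", n)
    if (any(edges[, 1L] == edges[, 2L]))
      stopf("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    dup <- duplicated(edges)
    if (any(dup)) edges <- edges[!dup, , drop = FALSE]
  }
  if (!is.null(labels) && length(labels) != n)
    stopf("labels must have length n_regions")
  structure(list(n = n, edges = edges, labels = labels),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("region_graph: %d regions, %d edges, %d connected component(s)\n",
              x$n, nrow(x$edges), max(graph_components(x))))
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Builds an `nrows` by `ncols` rectangular lattice in which each cell is a
#' region and cells sharing an edge (rook moves) are neighbors. A 19x19
#' lattice (361 regions) is the default study graph for the simulation
#' experiments, standing in for a real administrative adjacency map of
#' comparable size.
#'
#' @param nrows,ncols lattice dimensions; their product must be at least 2.
#' @return A [region_graph] with `nrows * ncols` regions, numbered row by
#'   row.
#' @examples
#' build_lattice_graph(2, 2)  # 4 regions, 4 edges
#' @export
build_lattice_graph <- function(nrows, ncols) {
  if (!is.numeric(nrows) || !is.numeric(ncols) || nrows < 1 || ncols < 1 ||
      nrows != round(nrows) || ncols != round(ncols))
    stopf("nrows and ncols must be positive integers")
  if (nrows * ncols < 2) stopf("lattice must contain at least 2 cells")
  idx <- function(r, c) (r - 1L) * ncols + c
  horiz <- NULL; vert <- NULL
  if (ncols > 1) {
    r <- rep(seq_len(nrows), each = ncols - 1L)
    c <- rep(seq_len(ncols - 1L), times = nrows)
    horiz <- cbind(idx(r, c), idx(r, c + 1L))
  }
  if (nrows > 1) {
    r <- rep(seq_len(nrows - 1L), each = ncols)
    c <- rep(seq_len(ncols), times = nrows - 1L)
    vert <- cbind(idx(r, c), idx(r + 1L, c))
  }
  region_graph(nrows * ncols, rbind(horiz, vert))
}

#' Connected components of a region graph
#'
#' @param graph a [region_graph].
#' @return Integer vector of length `graph$n` giving a 1-based component id
#'   per region.
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  n <- graph$n
  adj <- adjacency_list(graph)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n)
  for (k in seq_len(graph$n)) adj[[k]] <- integer(0)
  e <- graph$edges
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1L]; j <- e[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

#' Read a region graph from a text file
#'
#' Two dialects are supported: a plain whitespace-separated two-column edge
#' list (one `i j` pair per line, 1-based), and the INLA-style graph format
#' whose first line is the number of regions `n` followed by one line per
#' region: `i k j1 ... jk` where `k` is the number of neighbors of region
#' `i`. INLA-style files must list neighbors symmetrically; an asymmetric
#' pair is rejected with an error naming it.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"inla_graph"`.
#' @return A [region_graph].
#' @seealso [write_graph()]
#' @export
read_graph <- function(path, format = c("edge_list", "inla_graph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("graph file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "edge_list") {
    toks <- lapply(lines, function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]]))
    bad <- which(vapply(toks, length, 1L) != 2L)
    if (length(bad))
      stopf("edge list line %d does not have two fields", bad[1L])
    e <- do.call(rbind, toks)
    region_graph(max(e), e)
  } else {
    n <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]][1L])
    if (is.na(n) || n < 1) stopf("invalid region count on line 1")
    nbrs <- vector("list", n)
    for (l in lines[-1L]) {
      f <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      i <- f[1L]; k <- f[2L]
      if (is.na(i) || i < 1L || i > n)
        stopf("region index %s out of range [1, %d]", f[1L], n)
      js <- if (k > 0L) f[3L:(2L + k)] else integer(0)
      if (length(js) != k || anyNA(js))
        stopf("neighbor count mismatch for region %d", i)
      if (any(js < 1L | js > n))
        stopf("neighbor index out of range for region %d", i)
      nbrs[[i]] <- js
    }
    for (i in seq_len(n)) for (j in nbrs[[i]])
      if (!(i %in% nbrs[[j]]))
        stopf("asymmetric neighbor listing: %d lists %d but not vice versa",
              i, j)
    e <- do.call(rbind, lapply(seq_len(n), function(i) {
      js <- nbrs[[i]][nbrs[[i]] > i]
      if (length(js)) cbind(i, js) else NULL
    }))
    if (is.null(e)) e <- matrix(integer(0), ncol = 2L)
    region_graph(n, e)
  }
}

#' Write a region graph to a text file
#'
#' @inheritParams read_graph
#' @param graph a [region_graph].
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("edge_list", "inla_graph")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "region_graph"))
  if (format == "edge_list") {
    writeLines(apply(graph$edges, 1L, paste, collapse = " "), path)
  } else {
    adj <- adjacency_list(graph)
    lines <- c(as.character(graph$n),
               vapply(seq_len(graph$n), function(i) {
                 js <- sort(adj[[i]])
                 paste(c(i, length(js), js), collapse = " ")
               }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Intrinsic CAR precision matrix
#'
#' Constructs the (unscaled) intrinsic conditional autoregression precision
#' `Q = D - A`, the graph Laplacian: `D` is the diagonal matrix of neighbor
#' counts and `A` the adjacency matrix. `Q` is symmetric positive
#' semi-definite with zero row sums; its rank deficiency equals the number
#' of connected components, and the implied Gaussian Markov random field is
#' identified through a sum-to-zero constraint per component.
#'
#' @param graph a [region_graph] with at least 2 regions.
#' @return A sparse symmetric `Matrix::dsCMatrix`.
#' @examples
#' icar_precision(region_graph(2, rbind(c(1, 2))))
#' @export
icar_precision <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  if (graph$n < 2) stopf("need at least 2 regions")
  e <- graph$edges
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = graph$n)
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(graph$n), e[, 1L], e[, 2L]),
    j = c(seq_len(graph$n), e[, 2L], e[, 1L]),
    x = c(as.numeric(deg), rep(-1, 2L * nrow(e))),
    dims = c(graph$n, graph$n))
  methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
}

#' Scale an intrinsic CAR precision matrix
#'
#' Rescales the ICAR precision so that the geometric mean of the marginal
#' variances of the corresponding Gaussian Markov random field (under the
#' per-component sum-to-zero constraint) equals one: `Q* = c Q` with
#' `c = exp(mean(log diag((Q)^-)))`, the generalized inverse taken on the
#' sum-to-zero subspace. After scaling, a prior placed on the structured
#' effect's precision has the same meaning on any graph, which is the point
#' of the BYM2 parameterization. Scaling (and the constraint) is applied
#' per connected component; isolated regions are rejected since a
#' zero-degree region has no ICAR distribution.
#'
#' @param Q an ICAR precision matrix from [icar_precision()], or a
#'   [region_graph] (converted internally).
#' @return An object of class `scaled_precision`: `Q`, `Q_star`, `scale_c`
#'   (one scaling constant per connected component), `gen_inverse_diag`
#'   (marginal variances under `Q*`), `comp` (component membership), and an
#'   `eigen` element holding the eigendecomposition of `Q*` used by the
#'   samplers and the PC prior for the mixing parameter (`vectors`,
#'   `values`, `xi` = eigenvalues of the generalized inverse, `is_null`
#'   flags for per-component constant directions).
#' @references Riebler et al. (2016) "An intuitive Bayesian spatial model
#'   for disease mapping that accounts for scaling", Stat Methods Med Res.
#' @export
scale_icar <- function(Q) {
  if (inherits(Q, "region_graph")) {
    graph <- Q
    Q <- icar_precision(graph)
    comp <- graph_components(graph)
  } else {
    Q <- methods::as(Q, "CsparseMatrix")
    comp <- components_from_Q(Q)
  }
  n <- nrow(Q)
  if (any(Matrix::diag(Q) == 0))
    stopf("graph has isolated region(s): %s",
          paste(which(Matrix::diag(Q) == 0), collapse = ", "))
  ncomp <- max(comp)
  V <- matrix(0, n, n)
  values <- numeric(n)
  xi <- numeric(n)
  is_null <- logical(n)
  gid <- numeric(n)      # marginal variances under Q* (per region)
  scale_c <- numeric(ncomp)
  col0 <- 0L
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    m <- length(idx)
    if (m < 2) stopf("connected component %d has a single region", k)
    eg <- eigen(as.matrix(Q[idx, idx, drop = FALSE]), symmetric = TRUE)
    lam <- eg$values
    lam[m] <- 0                      # exactly one null direction per component
    if (m > 1 && any(lam[-m] < 1e-10 * max(lam)))
      stopf("unexpected extra null eigenvalue in component %d", k)
    xi_c <- c(1 / lam[-m], 0)
    mv <- rowSums(sweep(eg$vectors^2, 2L, xi_c, `*`))
    cc <- exp(mean(log(mv)))
    scale_c[k] <- cc
    cols <- col0 + seq_len(m)
    V[idx, cols] <- eg$vectors
    values[cols] <- lam * cc         # eigenvalues of Q* block
    xi[cols] <- xi_c / cc            # gen-inverse eigenvalues of Q*
    is_null[cols] <- c(rep(FALSE, m - 1L), TRUE)
    gid[idx] <- mv / cc
    col0 <- col0 + m
  }
  structure(list(Q = Q, Q_star = scale_Q_by_comp(Q, scale_c, comp),
                 scale_c = scale_c, gen_inverse_diag = gid, comp = comp,
                 n = n,
                 eigen = list(vectors = V, values = values, xi = xi,
                              is_null = is_null)),
            class = "scaled_precision")
}

# multiply rows/cols of each diagonal block by its component scale; Q has no
# cross-component entries so row scaling alone is exact and keeps symmetry
scale_Q_by_comp <- function(Q, scale_c, comp) {
  s <- scale_c[comp]
  Matrix::forceSymmetric(Matrix::Diagonal(x = s) %*% Q)
}

components_from_Q <- function(Q) {
  n <- nrow(Q)
  Qt <- methods::as(Q, "TsparseMatrix")
  off <- Qt@i[Qt@x != 0 & Qt@i != Qt@j] + 1L
  offj <- Qt@j[Qt@x != 0 & Qt@i != Qt@j] + 1L
  keep <- off < offj
  region_graph(n, cbind(off[keep], offj[keep])) |> graph_components()
}

#' @export
print.scaled_precision <- function(x, ...) {
  cat(sprintf(
    "scaled_precision: %d regions, %d component(s), scale c = %s\n",
    x$n, max(x$comp), paste(signif(x$scale_c, 5), collapse = ", ")))
  invisible(x)
}

#' Sample a constrained scaled ICAR effect
#'
#' Draws one realization of the intrinsic GMRF with precision `tau * Q*`
#' under the sum-to-zero constraint (per connected component). The draw is
#' made in the eigenbasis of `Q*`: coordinates along non-null eigenvectors
#' are independent normals with variance `xi_j / tau`, null directions are
#' fixed at zero, so the constraint holds by construction.
#'
#' @param sp a `scaled_precision` from [scale_icar()].
#' @param tau positive precision multiplier.
#' @param rng_seed integer seed; every stochastic function in this package
#'   takes an explicit seed rather than consuming global RNG state.
#' @return Numeric vector of length `n` summing to zero per component.
#' @export
sample_structured <- function(sp, tau, rng_seed) {
  stopifnot(inherits(sp, "scaled_precision"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stopf("tau must be a positive scalar")
  eg <- sp$eigen
  nn <- !eg$is_null
  z <- with_local_seed(rng_seed, rnorm(sum(nn)))
  drop(eg$vectors[, nn, drop = FALSE] %*% (z * sqrt(eg$xi[nn] / tau)))
}
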