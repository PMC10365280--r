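# Shared fixtures: small grids keep the suite fast; the phantom is
# deterministic given seeds, so everything is built in code at test time.

small_grid <- function(n = 24, spacing = 8) grid_spec(rep(n, 3L), spacing)

# cached phantom for tests that only need a template (64^3, 3 mm)
reg_phantom <- local({
  ph <- NULL
  function() {
    if (is.null(ph)) ph <<- make_template_phantom(grid_spec(c(64, 64, 64), 3),
                                                  seed = 1)
    ph
  }
})

# cached null stats cohort on the 24^3 grid
null_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co))
      co <<- make_cohort(10, seed = 1, grid = small_grid(),
                         params = dose_params(effect_size = 0),
                         template_space = TRUE)
    co
  }
})

rand_volume <- function(d = c(8, 8, 8), spacing = 4, seed = 99) {
  set.seed(seed)
  volume(array(stats::rnorm(prod(d)), d),
         doseatlas:::grid_affine(grid_spec(d, spacing)))
}

# independent brute-force TFCE oracle: explicit threshold loop with
# igraph connected components (not the package's union-find)
neighbor_pairs <- function(d, connectivity = 26) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  out <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
    a <- which(ok)
    b <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    keep <- a < b
    out[[r]] <- cbind(a[keep], b[keep])
  }
  do.call(rbind, out)
}

tfce_bruteforce <- function(stat, E, H, dh, nsteps, connectivity = 26) {
  d <- dim(stat)
  pairs <- neighbor_pairs(d, connectivity)
  sv <- as.vector(stat)
  out <- numeric(length(sv))
  for (s in seq_len(nsteps)) {
    h <- s * dh
    sup <- sv >= h
    if (!any(sup)) next
    keep <- sup[pairs[, 1]] & sup[pairs[, 2]]
    g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(sv) - igraph::vcount(g)))
    comp <- igraph::components(g)
    memb <- comp$membership
    sizes <- tabulate(memb[sup])
    out[sup] <- out[sup] + sizes[memb[sup]]^E * h^H * dh
  }
  array(out, d)
}
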